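---
title: "Quantifying larval zebrafish rheotaxis in a radial suction flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval zebrafish rheotaxis in a radial suction flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheopipe)
library(dplyr)
```

## The behavior and the assay

Larval zebrafish placed in a flow orient into the current and swim against
it to hold position (positive rheotaxis). `rheopipe` analyzes this behavior
in a radial assay: a suction point draws water radially inward over a
shallow platform, and larvae are filmed from above at 250 Hz, 35 µm/pixel.
A trajectory shows two phases: *exploration*, with bouts in random
directions, and a *counterflow swim sequence* (CSS), a run of bouts aimed
against the flow that holds the radial position.

The flow model is a depth-averaged two-dimensional point sink. With
volumetric rate $Q_v$ and depth $h$, the surfacic rate is
$q = Q_v / (2\pi h)$ and the fluid speed at distance $\rho$ from the sink
is $q/\rho$, purely radial. Walls, the platform edge and the vertical
dimension are ignored; this is the same idealization under which the
passive-reorientation equation below is derived, so the simulator and the
baseline model are consistent with each other.

Positions are described in polar coordinates $(\rho, \theta)$ about the
suction point. The body angle $\alpha$ is measured from the **outward**
radial direction to the head direction, wrapped to $(-\pi, \pi]$:
$\alpha = 0$ means perfect counterflow orientation. This convention is
anchored by the bout model (below), in which a bout displaces the larva
radially by $+\lambda u \cos\alpha$ — a counterflow bout must increase
$\rho$. The opposite convention (measuring from the inward direction)
cannot satisfy that sign.

## The measurement chain

**Segmentation.** Each frame is background-subtracted (the background is
the pixel-wise mean image of the run), smoothed with a Gaussian kernel
(175 × 175 µm box, σ = 50 µm, converted to pixels and rounded up to an odd
count), thresholded, and decomposed into 4-connected components; blobs
under 500 pixels (about half a larva) are discarded. The threshold default
is Otsu's method on the smoothed difference image, guarded by a noise floor
of six robust SDs so that empty frames do not segment noise; a fixed
threshold can be supplied instead. The whole-body centroid is computed on
the *binarized* body: the smoothing attenuates the thin tail's intensity,
and intensity weighting would bias the centroid toward the head by about
two pixels.

**Posture.** The blob's equivalent ellipse (the ellipse sharing its
intensity-weighted moments) defines a major axis; splitting the blob by the
line through the centroid perpendicular to that axis gives two halves whose
own equivalent ellipses describe head and tail. The head is the heavier
half whenever the area margin is decisive (> 15% relative difference);
within the margin the half nearer the previous head position is used. We
deliberately do not let continuity alone decide: a continuity-only rule is
self-consistent under a flip, and in measured sessions a single
mis-assignment then propagates for seconds (the body angle locks near
$\pi$ and impulse fits collapse to zero). The signed curvature comes from
the intersection of the two ellipses' minor axes (the center of curvature);
the radius of curvature is the mean distance from that center to all body
pixels, and the sign is positive when the center lies right of the head
direction. Near-parallel minor axes (within 0.5°) give a straight body,
$\kappa = 0$.

With this estimator, noiseless rendered bodies are recovered to within one
pixel in position, 2° in heading for straight bodies, and 10% in $|\kappa|$
for arcs up to 0.5 mm⁻¹. For bent bodies the head-ellipse axis is the head
half's chord, which deviates from the midline tangent by $O(\kappa L/4)$ —
the measured $\alpha$ therefore oscillates during tail beats, which is a
property of the moment-based estimator itself, not noise.

**Tracking.** Detections are linked frame to frame by exact minimization of
the total squared displacement (branch-and-bound over the gated candidate
sets; per-frame detection counts are small enough that the exact optimum is
cheap), with a maximal displacement of 3.5 mm and a dormancy memory of 100
frames (400 ms). Gap frames are left absent — downstream fits use observed
samples only. Track curation is automatic: minimum duration and a contact
radius at which overlapping larvae are truncated.

## Bouts and the impulse model

Swim bouts are detected on the curvature trace: the derivative
$\dot\kappa$ (central differences, reflected ends), its SD over a centered
20 ms window, normalized by a quiet baseline — within each centered 400 ms
window, the mean of the sub-median sliding-SD values. A bout is a run of
normalized activity above 5 lasting more than 40 ms. The ratio is
scale-invariant, so the detector is indifferent to curvature units and
offsets. Within a bout, tail beats are excursions of the curvature
(relative to its pre-bout 100 ms baseline) beyond 0.1 mm⁻¹ in absolute
value, counted once per opposite-sign pair; the beat period
$\tau_b$ is the mean same-sign peak-to-peak interval.

The impulse start $t_k$ is the time of minimal $\rho$ inside the bout
interval. The preceding 100 ms give the fluid speed $v_f$ by an affine fit
(reported positive toward the sink). The following window (300 ms,
truncated at the next bout) is fitted by the Stokes-drag impulse response

$$\rho(t) = \rho(t_k) + \lambda\, u \cos\alpha\,(1 - e^{-(t-t_k)/\lambda})
  - v_f (t - t_k),$$

with the impulse speed $u \ge 0$ and the damping time
$\lambda \in [4, 500]$ ms free ($v_f$ and $\alpha$ fixed), by bounded
Levenberg–Marquardt with multi-starts at $\lambda \in \{20, 40, 80\}$ ms.
Three numerical choices matter in noise: the model's $\rho(t_k)$ anchor is
taken from the affine fit's value at $t_k$ rather than the observed minimum
(the minimum of noisy samples is biased low by selection); $\alpha$ at
onset is read at $t_k$ rather than at the detected interval start (the
centered windows make the interval begin a few samples before the
impulse); and the onset/offset angles are 5-frame circular means, which
reject single-frame glitches in the resolved head direction. Note also a
structural limit of the minimum-$\rho$ rule: a bout whose impulse is too
weak to outrun the drift within its interval has its minimum at the
interval end, so $t_k$ — and hence the fit — is ill-defined for such
bouts by construction.
On noiseless model traces the fit recovers $(u, \lambda)$ to relative
error below $10^{-6}$; with 1-pixel Gaussian noise on $\rho$ at 250 Hz the
median relative errors are a few percent in $u$ and under 15% in
$\lambda$.

Successive bouts define the inter-bout period $\tau_k = t_{k+1} - t_k$ and
distance $\delta_k = \rho_{k+1} - \rho_k$; $\delta \approx 0$ is position
holding.

## Passive reorientation

An elongated inert body in the sheared radial flow experiences a
Jeffery-type torque; near the sink its angular speed is approximated by

$$\dot\alpha = s\,\frac{qL}{\rho}\,\sin\alpha,$$

valid for $\rho \gg L$ ($L$ the body length), integrated together with the
advection $\dot\rho = -q/\rho$ (adaptive `lsodar`, rtol $10^{-9}$ / atol
$10^{-12}$, stopping at $\rho \le L$). The sign $s$ is exposed because the
convention under which the equation aligns bodies *into* the flow is not
derivable from its bare form: with our outward-radial $\alpha$ and
$s = +1$ ("printed"), $|\alpha| = \pi$ is the attractor; with $s = -1$
("zero-attracting") the counterflow orientation $\alpha = 0$ is stabilized,
which is the hydromechanically expected behavior for this assay (the torque
assists orientation locking during counterflow swim). The passive module
defaults to the printed form; the session generator defaults to the
zero-attracting form, as its trajectories are meant to emulate real larvae.
With advection disabled, $\rho$ is frozen and the closed form
$\tan(\alpha/2) = \tan(\alpha_0/2)\,e^{s q L t / \rho_0}$ holds, which the
integrator matches to $10^{-6}$ rad over 10 s — this is the correctness
oracle for the module.

## The synthetic session generator

No recordings are distributed with the assay, so the generator is the
package's source of ground-truthed data, and its defaults are the study
conditions of every test. It emulates, per larva:

* **Exploration**: bouts at 1.2 s⁻¹ (exponential gaps), each drawing a new
  heading uniformly on $(-\pi, \pi]$ and an impulse speed of
  18 mm/s ± 25%.
* **CSS trigger**: the first bout after the larva first drifts inside the
  trigger radius (default 8 mm in the full-size arena) starts the CSS,
  after a 0.1 s latency.
* **CSS**: bouts every 0.7 s ± 12% aimed at the outward radial direction
  ± 10°, whose impulse is computed to cancel the upcoming inter-bout
  advection (position holding), ± 10%.
* **Bout mechanics**: damping time $\lambda$ = 40 ms ± 15% (truncated to
  [20, 100] ms), tail beats as a signed sinusoid of $n$ periods
  ($n \sim 2 + \text{Poisson}$, mean 4, capped at 6) at period
  $\tau_b$ = 30 ms ± 20%, amplitude $\frac{\pi}{2}\times$ 0.3 mm⁻¹ so the
  bout-mean $|\kappa|$ is 0.3 mm⁻¹. Bout durations are therefore
  0.06–0.22 s at a ~30 Hz beat frequency, the realistic glide-dominated
  regime; we verified that bouts beyond ~0.24 s would saturate the
  detector's 400 ms sub-median baseline, i.e. such schedules are
  inconsistent with the stated detector.
* **Between bouts**: advection $\dot\rho = -q/\rho$ plus passive
  reorientation (zero-attracting sign), midpoint-rule integration on the
  frame grid. The passive torque is suspended while the tail beats: the
  torque model describes an inert body, and during a bout the heading is
  actively held by the motor program.

All randomness flows from one session seed through named substreams
(initialization, scheduling, kinematics, render jitter, render noise), so
sessions are bit-reproducible and the renderer can be re-run on any frame
subset with identical output.

The renderer draws each larva as a bright bent rod on a dark background:
the midline is a circular arc with the pose's curvature, the half-width
profile tapers from a wide head lobe (the front 40% of the 4 mm body) to a
thin tail, edges are anti-aliased over one pixel, and the ground-truth
position is defined as the body's area centroid — the quantity segmentation
actually measures. Noise is additive Gaussian intensity noise (σ = 0.02 of
full scale) plus half-pixel positional jitter; the ground truth stays
clean.

What the generator does **not** emulate: hydrodynamic fish–fluid coupling,
3-D depth and focus blur, illumination gradients, wall effects, multi-larva
interaction, and any age dependence. Passing tests therefore demonstrate
that the measurement chain recovers what the model of the data contains —
they do not validate the detector against real video artifacts such as
occlusions or reflections.

## Population statistics

The circular variance $\mathrm{var}_c = 1 - |\langle e^{i\alpha}\rangle|$
summarizes orientation dispersion (0 = aligned, 1 = dispersed). CSS onsets
are labeled automatically: the first bout starting a run of at least 3
consecutive bouts with $|\alpha_{\text{offset}}| \le 45°$ and
$u\cos\alpha_{\text{onset}} > 0$ (all three parameters exposed).
Quality-flagged detections — intervals without tail beats, unfit or
non-converged impulse fits — are not bouts and are excluded from the
sequence before the run rule is applied and from the pooled transition
statistics; leaving them in lets a single spurious fragment break an
otherwise clear counterflow run and delay the detected onset. The
orientation transition is the circular variance of bout-onset angles in
0.5 s bins from 10 s before to 10 s after each track's onset; per-frame
pooling is available as an option. Bins with fewer than 3 samples are
masked. Note the estimator's small-sample bias: for $n$ uniform angles
$E[\mathrm{var}_c] \approx 1 - 0.886/\sqrt{n}$, so sparsely populated bins
understate the dispersion; evaluations on small synthetic cohorts should
pool windows rather than read single bins.

Distributions of bout quantities use fixed-bandwidth Gaussian KDEs
(renormalized to integrate to 1 within $10^{-6}$); two-sample comparisons
use the Kolmogorov–Smirnov test (asymptotic p by default, exact small-n
optional) and Welch's t-test, with significance marked at $p < 10^{-3}$
and $p < 10^{-6}$. Position holding is summarized by binning $\delta_k$
against $\rho_k$ (mean ± SE, bins under 3 pairs masked), CSS initiation by
the group means of $\rho_1$ and $v_1$ at each track's onset bout plus a KS
test of $\rho_1$ against radii of uniformly drawn field-of-view positions,
and the egocentric view by the 2-D density of the suction point in the
larva's head-forward frame.

## Problem sizes and numerical defaults

The test suite exercises the full chain at desk scale: round-trip renders
in the full 22 × 18 mm field of view; detector performance on ~20 simulated
tracks (≥ 200 scheduled bouts); a tracking audit with 10 larvae over 2500
frames; parameter recovery on 200 noiseless and 200 noisy impulse traces;
and a complete video-to-statistics run over three flow rates (4 larvae
each, 10 s at 250 Hz in a 12 × 10 mm arena with the trigger at 5 mm).
Tie-breaks and degeneracies are fixed as follows: assignment ties toward
the smallest track id; exact BSP area ties toward the smaller x centroid
(flagged); near-parallel minor axes give $\kappa = 0$; curvature magnitudes
are capped at 2 mm⁻¹ (flagged); impulse fits with fewer than 5 post-onset
samples are kept but flagged unfit.

## Known limitations

The moment-based $\alpha$ oscillates with tail beats (head-chord effect);
analyses that need a beat-free orientation should read $\alpha$ at bout
onsets, as the transition statistics do. The mean-image background assumes
each pixel is larva-free most of the time; a larva that lingers — and a
position-holding larva lingers by definition — leaves a ghost that locally
weakens detection. In the emulated assay the run average spans many
reinjection-randomized cycles and converges to the empty arena; a short
single-cycle synthetic session does not, so
`measure_session_poses(background = render_empty_background(...))`
supplies the larva-free reference that the multi-cycle average would
converge to. The CSS labeling criterion is a deliberate
automation of what was historically a manual curation step; its parameters
are exposed and should be reported alongside results.
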