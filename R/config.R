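#' Assay geometry and flow configuration
#'
#' Bundles the suction-flow assay parameters: the volumetric suction rate, the
#' water depth over the imaging platform, the suction-point location and the
#' imaged field of view. The radial fluid speed at distance `rho` from the
#' suction point is `q / rho` with the surfacic rate `q = Q_v / (2 * pi * h)`
#' (depth-averaged two-dimensional point-sink idealization; walls and the
#' platform edge are ignored).
#'
#' @param Q_v Volumetric flow rate, mm^3/s (0.07-0.66 mL/s in the assay;
#'   1 mL/s = 1000 mm^3/s). Must be >= 0.
#' @param h Water depth over the platform, mm (> 0).
#' @param sink Suction-point coordinates `c(x, y)` in the arena frame, mm.
#'   Must lie inside (or on the boundary of) the field of view.
#' @param fov Field of view as `c(x0, y0, width, height)` in mm.
#' @param frame_rate Acquisition rate, Hz (> 0).
#' @param pixel_size Pixel size, mm/pixel (> 0; 35 um = 0.035).
#'
#' @return An object of class `flow_config` (a named list).
#' @examples
#' cfg <- flow_config(Q_v = 220)
#' surfacic_rate(cfg)        # Q_v / (2 pi h), mm^2/s
#' flow_speed(8.75, cfg)     # ~1 mm/s
#' @export
flow_config <- function(Q_v = 220, h = 4,
                        fov = c(0, 0, 22, 18),
                        sink = c(fov[1] + fov[3] / 2, fov[2] + fov[4] / 2),
                        frame_rate = 250, pixel_size = 0.035) {
  stopifnot(length(fov) == 4, length(sink) == 2)
  if (!is.finite(Q_v) || Q_v < 0) abort("`Q_v` must be >= 0.")
  if (!is.finite(h) || h <= 0) abort("`h` must be > 0.")
  if (frame_rate <= 0) abort("`frame_rate` must be > 0.")
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (fov[3] <= 0 || fov[4] <= 0) abort("`fov` width and height must be > 0.")
  inside <- sink[1] >= fov[1] && sink[1] <= fov[1] + fov[3] &&
    sink[2] >= fov[2] && sink[2] <= fov[2] + fov[4]
  if (!inside) abort("`sink` must lie inside or on the boundary of `fov`.")
  structure(
    list(Q_v = Q_v, h = h, sink = as.numeric(sink), fov = as.numeric(fov),
         frame_rate = frame_rate, pixel_size = pixel_size),
    class = "flow_config"
  )
}

#' @export
print.flow_config <- function(x, ...) {
  cat("<flow_config>\n")
  cat(sprintf("  Q_v: %g mm^3/s   h: %g mm   q: %.4g mm^2/s\n",
              x$Q_v, x$h, surfacic_rate(x)))
  cat(sprintf("  sink: (%g, %g) mm   fov: [%g, %g] + %g x %g mm\n",
              x$sink[1], x$sink[2], x$fov[1], x$fov[2], x$fov[3], x$fov[4]))
  cat(sprintf("  frame_rate: %g Hz   pixel_size: %g mm/px\n",
              x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Surfacic flow rate
#'
#' `q = Q_v / (2 * pi * h)`, the depth-averaged strength of the point sink in
#' mm^2/s.
#'
#' @param config A [flow_config()].
#' @return Numeric scalar, mm^2/s.
#' @export
surfacic_rate <- function(config) config$Q_v / (2 * pi * config$h)

#' Radial fluid speed at distance rho from the suction point
#'
#' The depth-averaged sink flow is purely radial with speed `q / rho`, `q`
#' being the surfacic rate. Speed decreases as `1/rho` and is linear in the
#' volumetric rate.
#'
#' @param rho Radial distance(s) from the suction point, mm (> 0).
#' @param config A [flow_config()].
#' @return Fluid speed(s), mm/s (magnitude; the flow points toward the sink).
#' @examples
#' flow_speed(8.75, flow_config(Q_v = 220, h = 4))  # ~1.00 mm/s
#' @export
flow_speed <- function(rho, config) {
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    abort("`rho` must be finite and > 0.")
  }
  surfacic_rate(config) / rho
}

default_width_profile <- function() {
  # half-width (mm) vs normalized arclength, 0 = tail tip, 1 = snout;
  # the head lobe (front ~40% of the body) is markedly wider so that the
  # heavier BSP half identifies the head
  tibble(
    s = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
    halfwidth = c(0.06, 0.08, 0.09, 0.10, 0.11, 0.13, 0.16,
                  0.24, 0.29, 0.27, 0.14)
  )
}

#' Larva body model
#'
#' Geometric and photometric model of a larva used by the synthetic renderer
#' and by the passive-reorientation equation: a bent rod of length `L` whose
#' half-width varies along the body, brighter than the dark background.
#'
#' @param L Body length, mm (> 0). ~4 mm for 5-9 dpf larvae.
#' @param head_fraction Fraction of the body length occupied by the head lobe,
#'   in (0, 1). The head end is at normalized arclength 1.
#' @param width_profile Data frame with columns `s` (normalized arclength in
#'   [0, 1], 0 = tail tip) and `halfwidth` (mm, strictly positive); linearly
#'   interpolated.
#' @param intensity Peak brightness of the rendered body on a [0, 1] scale.
#'
#' @return An object of class `larva_model`.
#' @export
larva_model <- function(L = 4, head_fraction = 0.4,
                        width_profile = default_width_profile(),
                        intensity = 0.8) {
  if (!is.finite(L) || L <= 0) abort("`L` must be > 0.")
  if (head_fraction <= 0 || head_fraction >= 1) {
    abort("`head_fraction` must be in (0, 1).")
  }
  stopifnot(all(c("s", "halfwidth") %in% names(width_profile)))
  if (any(width_profile$halfwidth <= 0)) {
    abort("`width_profile$halfwidth` must be strictly positive.")
  }
  structure(
    list(L = L, head_fraction = head_fraction,
         width_profile = as_tibble(width_profile), intensity = intensity),
    class = "larva_model"
  )
}

# interpolated half-width at normalized arclength s in [0, 1]
larva_halfwidth <- function(larva, s) {
  approx(larva$width_profile$s, larva$width_profile$halfwidth,
         xout = pmin(pmax(s, 0), 1), rule = 2)$y
}

#' Segmentation parameters
#'
#' Parameters of the per-frame detection step: Gaussian smoothing of the
#' background-subtracted image, thresholding and a minimum-area filter.
#'
#' @param blur_box Side of the square smoothing kernel, um (rounded up to an
#'   odd pixel count at the frame's pixel size).
#' @param blur_sigma Gaussian sigma, um (> 0).
#' @param threshold Fixed intensity threshold on the smoothed difference
#'   image, or `"auto"` for Otsu's method (guarded by a noise floor of
#'   6 robust SDs of the difference image).
#' @param min_area Minimum blob area in pixels (> 0); smaller objects are
#'   discarded (500 px is about half a larva at 35 um/px).
#'
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(blur_box = 175, blur_sigma = 50,
                                threshold = "auto", min_area = 500) {
  if (blur_sigma <= 0) abort("`blur_sigma` must be > 0.")
  if (min_area <= 0) abort("`min_area` must be > 0.")
  if (!identical(threshold, "auto") && !is.numeric(threshold)) {
    abort("`threshold` must be a number or \"auto\".")
  }
  structure(
    list(blur_box = blur_box, blur_sigma = blur_sigma,
         threshold = threshold, min_area = min_area),
    class = "segmentation_params"
  )
}

#' Behavioral parameters of the synthetic session generator
#'
#' Defines the two-phase behavior the generator emulates: exploration (bouts
#' at a constant rate with uniformly random new headings) followed, once the
#' larva has drifted inside the trigger radius, by a counterflow swim sequence
#' (CSS: bouts aimed against the flow whose impulse compensates the inter-bout
#' advection, i.e. position holding).
#'
#' @param explore_rate Exploration bout rate, bouts/s (exponential inter-bout
#'   gaps).
#' @param trigger_rho CSS trigger radius, mm: the first bout after the larva
#'   first drifts inside this radius starts the CSS.
#' @param css_latency Delay between crossing the trigger radius and the CSS
#'   onset bout, s.
#' @param css_tau Mean CSS inter-bout period, s.
#' @param css_tau_cv Coefficient of variation of the CSS inter-bout period.
#' @param css_alpha_sigma SD of the CSS target body angle around the outward
#'   radial direction, rad.
#' @param u_mean,u_cv Mean and CV of the exploration bout impulse speed, mm/s.
#' @param hold_u_cv CV of the (drift-compensating) CSS impulse speed.
#' @param lambda_mean,lambda_cv Mean and CV of the Stokes-drag damping time
#'   scale lambda, s (truncated to [0.02, 0.1]).
#' @param n_mean Mean tail-beat count per bout (Poisson, truncated to
#'   [2, 6]).
#' @param tau_b Tail-beat period, s (~33 Hz beat frequency).
#' @param tau_b_cv CV of the tail-beat period.
#' @param kappa_mean Mean absolute curvature of the tail-beat oscillation,
#'   1/mm (sinusoid amplitude is `pi/2 * kappa_mean`).
#' @param reorient Passive reorientation between bouts: `"zero-attracting"`
#'   (hydromechanical stabilization of the counterflow orientation alpha = 0,
#'   the generator default), `"printed"` (the opposite sign, attracting
#'   |alpha| = pi under this package's outward-radial convention), or
#'   `"off"`.
#'
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(explore_rate = 1.2, trigger_rho = 8,
                            css_latency = 0.1, css_tau = 0.7,
                            css_tau_cv = 0.12, css_alpha_sigma = 0.17,
                            u_mean = 18, u_cv = 0.25, hold_u_cv = 0.1,
                            lambda_mean = 0.04, lambda_cv = 0.15,
                            n_mean = 4, tau_b = 0.03, tau_b_cv = 0.1,
                            kappa_mean = 0.3,
                            reorient = c("zero-attracting", "printed", "off")) {
  reorient <- match.arg(reorient)
  stopifnot(explore_rate >= 0, trigger_rho > 0, css_tau > 0,
            lambda_mean > 0, n_mean >= 1, tau_b > 0, kappa_mean >= 0)
  structure(
    list(explore_rate = explore_rate, trigger_rho = trigger_rho,
         css_latency = css_latency, css_tau = css_tau,
         css_tau_cv = css_tau_cv, css_alpha_sigma = css_alpha_sigma,
         u_mean = u_mean, u_cv = u_cv, hold_u_cv = hold_u_cv,
         lambda_mean = lambda_mean, lambda_cv = lambda_cv,
         n_mean = n_mean, tau_b = tau_b, tau_b_cv = tau_b_cv,
         kappa_mean = kappa_mean, reorient = reorient),
    class = "behavior_params"
  )
}

#' Rendering noise parameters
#'
#' @param intensity_sigma SD of additive Gaussian intensity noise on the
#'   [0, 1] scale.
#' @param pos_jitter SD of the per-frame positional jitter applied at render
#'   time, mm (about half a pixel by default); the ground truth stays clean.
#' @return An object of class `render_noise`.
#' @export
render_noise <- function(intensity_sigma = 0.02, pos_jitter = 0.0175) {
  stopifnot(intensity_sigma >= 0, pos_jitter >= 0)
  structure(list(intensity_sigma = intensity_sigma, pos_jitter = pos_jitter),
            class = "render_noise")
}
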