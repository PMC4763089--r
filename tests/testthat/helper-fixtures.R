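# Shared fixtures, all generated in code.

default_cfg <- function(...) flow_config(Q_v = 220, ...)

small_cfg <- function(Q_v = 220, ...) {
  flow_config(Q_v = Q_v, fov = c(0, 0, 10, 8), ...)
}

blank_bg <- function(config) {
  matrix(0, round(config$fov[4] / config$pixel_size),
         round(config$fov[3] / config$pixel_size))
}

# render one pose and segment it against a blank background
render_and_pose <- function(x, y, phi, kappa, larva = larva_model(),
                            config = default_cfg()) {
  fr <- render_pose(x, y, phi, kappa, larva, config)
  blobs <- segment_frame(fr, blank_bg(config), segmentation_params(), config)
  stopifnot(nrow(blobs) >= 1)
  pose_from_blob(blobs[1, ], config, t = 0)
}

# pixel table of an analytically filled ellipse (uniform intensity),
# semi-axes in mm, independent of the renderer
ellipse_pixels <- function(cx, cy, a, b, phi, pixel_size = 0.035,
                           extent = NULL) {
  if (is.null(extent)) extent <- 1.2 * a
  g <- seq(-extent, extent, by = pixel_size)
  gx <- rep(g, times = length(g))
  gy <- rep(g, each = length(g))
  xr <- gx * cos(phi) + gy * sin(phi)
  yr <- -gx * sin(phi) + gy * cos(phi)
  keep <- (xr / a)^2 + (yr / b)^2 <= 1
  tibble::tibble(x_mm = cx + gx[keep], y_mm = cy + gy[keep],
                 intensity = 1, row = NA_integer_, col = NA_integer_)
}

wrapped_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

unit_vec_test <- function(phi) c(cos(phi), sin(phi))

# synthetic curvature trace: quiet baseline with sinusoid bursts
burst_trace <- function(n, frame_rate, bursts, amplitude = 0.4,
                        period = 0.04, noise_sd = 0.005, seed = 1) {
  set.seed(seed)
  kappa <- rnorm(n, 0, noise_sd)
  t <- (seq_len(n) - 1) / frame_rate
  for (b in bursts) {
    sel <- t >= b[1] & t < b[2]
    kappa[sel] <- kappa[sel] +
      amplitude * sin(2 * pi * (t[sel] - b[1]) / period)
  }
  kappa
}

# noiseless Eq.1-style radial trace with an impulse at t_on
impulse_trace <- function(frame_rate = 250, t_total = 0.5, t_on = 0.1,
                          rho0 = 10, u = 20, lambda = 0.04, v_f = 1,
                          alpha = 0) {
  t <- seq(0, t_total, by = 1 / frame_rate)
  rho <- ifelse(
    t < t_on, rho0 + v_f * t_on - v_f * t,
    rheopipe:::rho_impulse_model(t - t_on, rho0, u, lambda, v_f, alpha)
  )
  list(t = t, rho = rho,
       interval = list(start = which.min(abs(t - t_on)),
                       end = which.min(abs(t - (t_on + 0.2)))))
}
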