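# ggplot2 views of the main result types.

#' Plot the circular-variance transition around the CSS onset
#'
#' @param data Output of [aligned_circvar()].
#' @param passive Optional output of [passive_circular_variance()] drawn as
#'   the inert-larva baseline (its `t_s` is taken relative to the onset).
#' @return A ggplot object.
#' @export
plot_aligned_circvar <- function(data, passive = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$t_rel_s,
                                          y = .data$var_c)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time from CSS onset (s)",
                  y = "circular variance of α")
  if (!is.null(passive)) {
    p <- p + ggplot2::geom_line(
      data = passive, ggplot2::aes(x = .data$t_s, y = .data$var_c),
      linetype = "dashed", color = "grey40"
    )
  }
  p
}

#' Plot the radial position-holding profile
#'
#' Mean inter-bout distance versus radial position; the dashed line at 0 is
#' perfect distance holding.
#'
#' @param data Output of [radial_profile()].
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$rho_mid_mm,
                                     y = .data$delta_mean_mm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$delta_mean_mm - .data$delta_se_mm,
      ymax = .data$delta_mean_mm + .data$delta_se_mm
    ), alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "ρ (mm)", y = "mean δ (mm)")
}

#' @export
autoplot.rheo_kde <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "probability density")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.rheo_egodensity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lateral_mm,
                                       y = .data$forward_mm,
                                       fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm, right +)", y = "forward (mm)",
                  fill = "density")
}

#' Plot session trajectories
#'
#' Trajectories in the arena with the suction point marked; colored by phase
#' when available.
#'
#' @param poses A pose table with `x_mm`, `y_mm`, `larva_id` (and optionally
#'   `phase`).
#' @param config A [flow_config()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(poses, config) {
  aes_base <- if ("phase" %in% names(poses)) {
    ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                 group = .data$larva_id, color = .data$phase)
  } else {
    ggplot2::aes(x = .data$x_mm, y = .data$y_mm, group = .data$larva_id)
  }
  ggplot2::ggplot(poses, aes_base) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = config$sink[1], y = config$sink[2],
                      shape = 4, size = 3) +
    ggplot2::coord_equal(
      xlim = c(config$fov[1], config$fov[1] + config$fov[3]),
      ylim = c(config$fov[2], config$fov[2] + config$fov[4])
    ) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
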