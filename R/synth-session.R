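#' Simulate a ground-truthed behavioral session
#'
#' Generates trajectories, bout schedules and per-frame phase labels for one
#' or more larvae in the radial suction flow. The generator emulates the
#' two-phase behavior the analysis assumes: an exploration phase (bouts at a
#' constant rate with uniformly random new headings) and, after the larva
#' first drifts inside the trigger radius, a counterflow swim sequence (CSS)
#' whose bouts aim against the flow and whose impulse compensates the
#' inter-bout advection (position holding).
#'
#' Between bouts the larva is advected toward the sink (`rho_dot = -q/rho`)
#' and passively reorients at the Jeffery-type rate `(q L / rho) sin(alpha)`
#' (sign per `params$reorient`). Each bout sets the heading instantaneously,
#' drives an impulse speed `u * exp(-(t - t_k)/lambda)` along it, and writes a
#' sinusoidal curvature waveform of `n` periods at period `tau_b` with
#' amplitude `pi/2 * kappa_mean` (so the mean absolute curvature over the bout
#' equals `kappa_mean`).
#'
#' With `params$explore_rate == 0` the larvae are inert: no bouts are ever
#' produced and the trajectories are purely passive drift.
#'
#' All randomness derives from `seed` through named substreams (scheduling,
#' kinematics), so two calls with identical arguments are identical.
#'
#' @param config A [flow_config()].
#' @param larva A [larva_model()].
#' @param params A [behavior_params()].
#' @param n_larvae Number of larvae (ignored when `init` is given).
#' @param duration Session duration, s.
#' @param seed Integer seed (required).
#' @param init Optional data frame of initial states with columns `x_mm`,
#'   `y_mm` and optionally `heading_rad`; positions outside the field of view
#'   are rejected with an error. When `NULL`, positions are drawn uniformly in
#'   the field of view at radii above `params$trigger_rho + 0.5` mm (falling
#'   back to the largest feasible annulus).
#'
#' @return An object of class `rheo_session`: a list with tibbles `poses`
#'   (frame, t_s, larva_id, x_mm, y_mm, heading_rad, kappa_per_mm, rho_mm,
#'   theta_rad, alpha_rad, phase) and `bouts` (larva_id, k, t_k_s, rho_k_mm,
#'   u_mm_s, lambda_s, n, tau_b_s, heading_target_rad, alpha_target_rad,
#'   phase), plus the configuration objects and the seed.
#' @examples
#' ss <- simulate_session(flow_config(), larva_model(), behavior_params(),
#'                        n_larvae = 1, duration = 4, seed = 1)
#' head(ss$poses)
#' @export
simulate_session <- function(config, larva, params = behavior_params(),
                             n_larvae = 1, duration = 20, seed,
                             init = NULL) {
  stopifnot(inherits(config, "flow_config"), inherits(larva, "larva_model"))
  if (missing(seed)) abort("`seed` must be supplied.")
  fr <- config$frame_rate
  n_frames <- max(2L, as.integer(round(duration * fr)))
  t_grid <- (seq_len(n_frames) - 1) / fr

  if (!is.null(init)) {
    init <- as_tibble(init)
    n_larvae <- nrow(init)
    out_x <- init$x_mm < config$fov[1] | init$x_mm > config$fov[1] + config$fov[3]
    out_y <- init$y_mm < config$fov[2] | init$y_mm > config$fov[2] + config$fov[4]
    if (any(out_x | out_y)) {
      abort("initial position(s) outside the field of view.")
    }
  }

  larvae <- lapply(seq_len(n_larvae), function(i) {
    st <- draw_initial_state(config, params, seed, i, init)
    simulate_larva(i, st, config, larva, params, t_grid, seed)
  })

  poses <- dplyr::bind_rows(lapply(larvae, `[[`, "poses"))
  bouts <- dplyr::bind_rows(lapply(larvae, `[[`, "bouts"))
  structure(
    list(poses = poses, bouts = bouts, config = config, larva = larva,
         params = params, seed = seed, duration = duration,
         n_frames = n_frames),
    class = "rheo_session"
  )
}

#' @export
print.rheo_session <- function(x, ...) {
  cat(sprintf(
    "<rheo_session> %d larva(e), %d frames at %g Hz, %d bouts (seed %s)\n",
    dplyr::n_distinct(x$poses$larva_id), x$n_frames, x$config$frame_rate,
    nrow(x$bouts), format(x$seed)))
  invisible(x)
}

draw_initial_state <- function(config, params, seed, i, init) {
  if (!is.null(init)) {
    heading <- if ("heading_rad" %in% names(init)) init$heading_rad[i] else {
      with_stream(seed, "init-heading", i, code = runif(1, -pi, pi))
    }
    return(list(pos = c(init$x_mm[i], init$y_mm[i]), phi = heading))
  }
  with_stream(seed, "init", i, code = {
    fov <- config$fov
    rho_lo <- params$trigger_rho + 0.5
    # largest radius reachable inside the fov (corner distance)
    corners <- rbind(
      c(fov[1], fov[2]), c(fov[1] + fov[3], fov[2]),
      c(fov[1], fov[2] + fov[4]), c(fov[1] + fov[3], fov[2] + fov[4])
    )
    rho_corner <- max(sqrt(rowSums((corners -
      matrix(config$sink, 4, 2, byrow = TRUE))^2)))
    if (rho_lo > rho_corner - 0.5) rho_lo <- 0.5 * rho_corner
    for (try in seq_len(5000)) {
      p <- c(runif(1, fov[1] + 0.3, fov[1] + fov[3] - 0.3),
             runif(1, fov[2] + 0.3, fov[2] + fov[4] - 0.3))
      if (sqrt(sum((p - config$sink)^2)) >= rho_lo) {
        return(list(pos = p, phi = runif(1, -pi, pi)))
      }
    }
    abort("could not draw an initial position inside the field of view.")
  })
}

# pre-drawn random innovations for one larva, by named substream
draw_innovations <- function(seed, i, params, duration) {
  max_bouts <- ceiling(duration * (params$explore_rate + 1 / params$css_tau)) + 20
  sched <- with_stream(seed, "scheduling", i, code = list(
    gap_expl = if (params$explore_rate > 0) {
      rexp(max_bouts, params$explore_rate)
    } else {
      rep(Inf, max_bouts)
    },
    z_tau = rnorm(max_bouts)
  ))
  kin <- with_stream(seed, "kinematics", i, code = list(
    heading = runif(max_bouts, -pi, pi),
    z_alpha = rnorm(max_bouts),
    z_u = rnorm(max_bouts),
    z_lambda = rnorm(max_bouts),
    n_pois = pmin(rpois(max_bouts, max(params$n_mean - 2, 0.1)) + 2L, 6L),
    z_tau_b = rnorm(max_bouts)
  ))
  list(sched = sched, kin = kin, max_bouts = max_bouts)
}

simulate_larva <- function(i, st, config, larva, params, t_grid, seed) {
  fr <- config$frame_rate
  dt <- 1 / fr
  n_frames <- length(t_grid)
  q <- surfacic_rate(config)
  L <- larva$L
  inn <- draw_innovations(seed, i, params, t_grid[n_frames] + dt)
  s_reorient <- switch(params$reorient,
    "zero-attracting" = -1, "printed" = 1, "off" = 0)
  kappa_amp <- pi / 2 * params$kappa_mean
  rho_stop <- max(1, L / 4)

  pos <- st$pos
  phi <- st$phi
  phase <- "exploration"
  css_pending_t <- NA_real_   # scheduled CSS onset time
  bouts_enabled <- params$explore_rate > 0

  k <- 0L
  bout <- NULL                 # active/last bout (list)
  next_bout_t <- if (bouts_enabled) inn$sched$gap_expl[1] else Inf
  gap_idx <- 1L

  x <- y <- heading <- kap <- rho_v <- theta_v <- alpha_v <- numeric(n_frames)
  phase_v <- character(n_frames)
  bout_rows <- vector("list", inn$max_bouts)

  flow_vel <- function(p) {
    d <- p - config$sink
    r <- sqrt(sum(d^2))
    if (r < 1e-6) return(c(0, 0))
    -(q / r) * d / r
  }

  for (f in seq_len(n_frames)) {
    t <- t_grid[f]
    d <- pos - config$sink
    rho <- sqrt(sum(d^2))
    theta <- atan2(d[2], d[1])
    alpha <- wrap_angle(phi - theta)

    # CSS trigger: first crossing of the trigger radius schedules the onset
    if (bouts_enabled && phase == "exploration" && is.na(css_pending_t) &&
        rho <= params$trigger_rho) {
      css_pending_t <- t + params$css_latency
      next_bout_t <- min(next_bout_t, css_pending_t)
    }

    # bout onset (snapped to the frame grid)
    if (bouts_enabled && t + dt / 2 >= next_bout_t && k < inn$max_bouts) {
      k <- k + 1L
      starts_css <- !is.na(css_pending_t) && phase == "exploration"
      if (starts_css) phase <- "css"
      if (phase == "css") {
        a_t <- wrap_angle(params$css_alpha_sigma * inn$kin$z_alpha[k])
        phi <- wrap_angle(theta + a_t)    # aim near the outward radial
      } else {
        phi <- inn$kin$heading[k]
        a_t <- wrap_angle(phi - theta)
      }
      lam <- params$lambda_mean * (1 + params$lambda_cv * inn$kin$z_lambda[k])
      lam <- min(max(lam, 0.02), 0.1)
      n_b <- max(2L, inn$kin$n_pois[k])
      tb <- params$tau_b * (1 + params$tau_b_cv * inn$kin$z_tau_b[k])
      tb <- min(max(tb, 0.8 * params$tau_b), 1.2 * params$tau_b)
      if (phase == "css") {
        tau_next <- params$css_tau * (1 + params$css_tau_cv * inn$sched$z_tau[k])
        tau_next <- max(tau_next, n_b * tb + 0.1)
        # impulse that cancels the upcoming inter-bout advection
        u <- flow_speed(max(rho, rho_stop), config) * tau_next /
          (lam * max(cos(a_t), 0.2))
        u <- u * max(1 + params$hold_u_cv * inn$kin$z_u[k], 0.2)
      } else {
        tau_next <- inn$sched$gap_expl[min(gap_idx + 1L, length(inn$sched$gap_expl))]
        gap_idx <- gap_idx + 1L
        tau_next <- max(tau_next, n_b * tb + 0.1)
        u <- max(params$u_mean * (1 + params$u_cv * inn$kin$z_u[k]), 2)
      }
      bout <- list(t_k = t, u = u, lambda = lam, n = n_b, tau_b = tb,
                   phi = phi, end = t + n_b * tb)
      bout_rows[[k]] <- tibble(
        larva_id = i, k = k, t_k_s = t, rho_k_mm = rho, u_mm_s = u,
        lambda_s = lam, n = n_b, tau_b_s = tb,
        heading_target_rad = phi, alpha_target_rad = a_t, phase = phase
      )
      next_bout_t <- t + tau_next
      alpha <- wrap_angle(phi - theta)
    }

    # curvature waveform of the active bout
    kv <- 0
    if (!is.null(bout) && t >= bout$t_k && t <= bout$end + dt / 4) {
      kv <- kappa_amp * sin(2 * pi * (t - bout$t_k) / bout$tau_b)
    }

    x[f] <- pos[1]; y[f] <- pos[2]; heading[f] <- phi; kap[f] <- kv
    rho_v[f] <- rho; theta_v[f] <- theta; alpha_v[f] <- alpha
    phase_v[f] <- phase

    # integrate to the next frame (midpoint rule)
    if (f < n_frames && rho > rho_stop) {
      imp <- function(tt) {
        if (is.null(bout) || tt < bout$t_k) return(c(0, 0))
        bout$u * exp(-(tt - bout$t_k) / bout$lambda) * unit_vec(bout$phi)
      }
      v1 <- flow_vel(pos) + imp(t)
      mid <- pos + v1 * dt / 2
      v2 <- flow_vel(mid) + imp(t + dt / 2)
      pos <- pos + v2 * dt
      # passive reorientation of the heading; suspended while the larva
      # beats its tail (the torque model applies to an inert body — during
      # a bout the heading is actively held by the motor program)
      beating <- !is.null(bout) && t >= bout$t_k && t < bout$end
      if (s_reorient != 0 && !beating) {
        dmid <- mid - config$sink
        rmid <- max(sqrt(sum(dmid^2)), rho_stop)
        a_mid <- wrap_angle(phi - atan2(dmid[2], dmid[1]))
        phi <- wrap_angle(phi + s_reorient * (q * L / rmid) * sin(a_mid) * dt)
      }
    }
  }

  list(
    poses = tibble(
      frame = seq_len(n_frames), t_s = t_grid, larva_id = i,
      x_mm = x, y_mm = y, heading_rad = heading, kappa_per_mm = kap,
      rho_mm = rho_v, theta_rad = theta_v, alpha_rad = alpha_v,
      phase = phase_v
    ),
    bouts = dplyr::bind_rows(bout_rows[seq_len(k)])
  )
}
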