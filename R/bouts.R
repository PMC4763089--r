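# Swim-bout detection from the curvature trace and per-bout kinematics.
#
# Detection: the sliding (20 ms) standard deviation of the curvature
# derivative, normalized by a quiet baseline (the mean of the sub-median
# values over a centered 400 ms window), crosses a threshold of 5 for more
# than 40 ms. Per bout, the impulse start t_k is the time of minimal rho
# inside the bout interval; the 100 ms before t_k give the fluid speed v_f
# by an affine fit, and the up-to-300 ms after t_k are fitted by the
# Stokes-drag impulse response
#   rho(t) = rho_k + lambda * u * cos(alpha) * (1 - exp(-(t - t_k)/lambda))
#            - v_f * (t - t_k)
# with u (impulse speed) and lambda (damping time) free.

#' Normalized bout activity from a curvature trace
#'
#' Computes the curvature derivative by central differences (reflected ends),
#' its standard deviation over a centered sliding window of 20 ms, and
#' normalizes by a robust quiet baseline: within each centered 400 ms window,
#' the mean of the sliding-SD values lying below that window's median.
#' Windows shrink at the trace ends. The ratio is scale-invariant: scaling
#' the curvature leaves the activity unchanged.
#'
#' @param kappa Curvature trace, 1/mm, regularly sampled.
#' @param frame_rate Sampling rate, Hz.
#' @return A tibble `activity` (dimensionless), `sigma_kdot`, `baseline`,
#'   `flag` (`"flat"` where the baseline is zero and activity is defined
#'   as 0).
#' @export
bout_activity <- function(kappa, frame_rate) {
  n <- length(kappa)
  if (n < ceiling(0.4 * frame_rate)) {
    abort("trace shorter than 400 ms; cannot form the baseline window.")
  }
  padded <- c(kappa[2], kappa, kappa[n - 1])       # reflected ends
  kdot <- (padded[3:(n + 2)] - padded[1:n]) * frame_rate / 2
  w_sd <- max(3L, round(0.02 * frame_rate))
  if (w_sd %% 2 == 0) w_sd <- w_sd + 1L
  sig <- zoo::rollapply(kdot, width = w_sd, FUN = sd, partial = TRUE,
                        align = "center")
  w_bl <- round(0.4 * frame_rate)
  if (w_bl %% 2 == 0) w_bl <- w_bl + 1L
  baseline <- zoo::rollapply(sig, width = w_bl, partial = TRUE,
                             align = "center", FUN = function(v) {
    m <- median(v)
    lo <- v[v < m]
    if (length(lo) == 0) m else mean(lo)
  })
  act <- ifelse(baseline > 0, sig / baseline, 0)
  tibble(activity = act, sigma_kdot = sig, baseline = baseline,
         flag = ifelse(baseline > 0, "", "flat"))
}

#' Detect bout intervals from an activity trace
#'
#' Maximal runs where the activity exceeds `threshold` for more than
#' `min_duration`.
#'
#' @param activity Activity values from [bout_activity()] (vector or its
#'   tibble).
#' @param frame_rate Sampling rate, Hz.
#' @param threshold Activity threshold (default 5).
#' @param min_duration Minimal duration, s (default 0.04; a run of m samples
#'   covers m / frame_rate seconds).
#' @return A tibble of disjoint, time-ordered intervals: `start`, `end`
#'   (sample indices, inclusive), `t_start_s`, `t_end_s` (times on the
#'   0-based sample grid).
#' @export
detect_bouts <- function(activity, frame_rate, threshold = 5,
                         min_duration = 0.04) {
  if (is.data.frame(activity)) activity <- activity$activity
  above <- activity > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / frame_rate > min_duration)
  tibble(
    start = starts[keep], end = ends[keep],
    t_start_s = (starts[keep] - 1) / frame_rate,
    t_end_s = (ends[keep] - 1) / frame_rate
  )
}

#' Count tail beats within a bout interval
#'
#' The relative curvature is the curvature minus its pre-bout baseline (mean
#' over the 100 ms before onset). Tail beats are excursions of the absolute
#' relative curvature above `beat_threshold`, counted once per pair of
#' opposite-sign excursions; the beat period is the mean interval between
#' consecutive same-sign excursion peaks.
#'
#' @param kappa Full curvature trace, 1/mm.
#' @param interval One row of [detect_bouts()] (or a list with `start`,
#'   `end`).
#' @param frame_rate Sampling rate, Hz.
#' @param beat_threshold Threshold on the absolute relative curvature
#'   (default 0.1).
#' @return A list: `n` (beats; 0 when none found, flagged), `tau_b_s` (mean
#'   beat period, NA when fewer than two same-sign peaks), `mean_abs_kappa`
#'   (mean absolute relative curvature over the interval), `flag`.
#' @export
count_tail_beats <- function(kappa, interval, frame_rate,
                             beat_threshold = 0.1) {
  i0 <- interval$start[1]; i1 <- interval$end[1]
  pre <- max(1, i0 - round(0.1 * frame_rate)):max(1, i0 - 1)
  base <- if (i0 > 1) mean(kappa[pre]) else 0
  rel <- kappa[i0:i1] - base
  over <- abs(rel) > beat_threshold
  if (!any(over)) {
    return(list(n = 0L, tau_b_s = NA_real_,
                mean_abs_kappa = mean(abs(rel)), flag = "no_beats"))
  }
  sgn <- sign(rel) * over
  r <- rle(as.integer(sgn))
  seg <- which(r$values != 0)
  seg_sign <- r$values[seg]
  # merge consecutive same-sign excursions (separated only by sub-threshold
  # samples) into one
  keep <- c(TRUE, seg_sign[-1] != seg_sign[-length(seg_sign)])
  merged <- seg[keep]
  m <- length(merged)
  n_beats <- as.integer(ceiling(m / 2))
  # peak time of each merged excursion
  ends_all <- cumsum(r$lengths)
  starts_all <- ends_all - r$lengths + 1
  grp <- cumsum(keep)
  peak_t <- vapply(seq_len(m), function(g) {
    segs <- seg[grp == g]
    lo <- starts_all[segs[1]]; hi <- ends_all[segs[length(segs)]]
    j <- lo:hi
    j[which.max(abs(rel[j]))]
  }, numeric(1))
  peak_sign <- seg_sign[keep]
  tau_b <- NA_real_
  for (s in c(1, -1)) {
    pk <- peak_t[peak_sign == s]
    if (length(pk) >= 2) {
      tau_b <- c(if (!is.na(tau_b)) tau_b, mean(diff(pk)) / frame_rate)
      tau_b <- mean(tau_b)
    }
  }
  list(n = n_beats, tau_b_s = tau_b, mean_abs_kappa = mean(abs(rel)),
       flag = "")
}

# circular mean of angles in a +-half window around index i (robust to
# single-sample glitches in the resolved head direction)
circ_mean_window <- function(a, i, n, half = 2) {
  w <- a[max(1, i - half):min(n, i + half)]
  atan2(mean(sin(w)), mean(cos(w)))
}

# Stokes-drag impulse response, t measured from the impulse start
rho_impulse_model <- function(tt, rho_k, u, lambda, v_f, alpha) {
  rho_k + lambda * u * cos(alpha) * (1 - exp(-tt / lambda)) - v_f * tt
}

#' Fit per-bout kinematics from the radial trace
#'
#' The impulse start `t_k` is the time of minimal rho within the bout
#' interval. An affine least-squares fit of rho on the 100 ms before `t_k`
#' gives the fluid speed `v_f` (reported positive toward the sink, i.e.
#' minus the fitted slope) and intercept; the model's `rho(t_k)` anchor is
#' the affine fit's value at `t_k` (the raw minimum of noisy samples is
#' biased low by selection). The window from `t_k` to at most
#' 300 ms later (truncated at the next bout start) is fitted by the
#' impulse-response model with `v_f` and `alpha` fixed, giving the impulse
#' speed `u >= 0` and damping time `lambda` in [4, 500] ms (bounded
#' Levenberg-Marquardt, multi-start at lambda = 20, 40, 80 ms).
#'
#' @param t Time stamps of the trace, s.
#' @param rho Radial positions, mm.
#' @param interval One row of [detect_bouts()] (sample indices into `t`).
#' @param alpha_onset Body angle at bout onset, rad (fixed in the fit).
#' @param next_bout_start Start index of the next bout (or `Inf`).
#' @param frame_rate Sampling rate, Hz.
#' @return A one-row tibble: `t_k_s`, `rho_k_mm`, `v_f_mm_s`, `c_mm`,
#'   `u_mm_s`, `lambda_s`, `fit_rms_mm`, `flag` (`"unfit"` when the
#'   post-window has fewer than 5 samples, `"no_converge"` when no start
#'   converges).
#' @export
fit_bout_kinematics <- function(t, rho, interval, alpha_onset,
                                next_bout_start = Inf, frame_rate) {
  i0 <- interval$start[1]; i1 <- interval$end[1]
  ik <- i0 - 1 + which.min(rho[i0:i1])
  t_k <- t[ik]
  rho_k <- rho[ik]

  pre <- which(t >= t_k - 0.1 & t <= t_k)
  v_f <- NA_real_; c_mm <- NA_real_
  if (length(pre) >= 3) {
    fit_pre <- lm(rho[pre] ~ t[pre])
    v_f <- -unname(coef(fit_pre)[2])   # positive toward the sink
    c_mm <- unname(coef(fit_pre)[1])
    # anchor rho(t_k) on the affine fit rather than the noisy observed
    # minimum (taking the minimum of noisy samples is biased low)
    rho_k <- c_mm - v_f * t_k
  }

  post_lim <- min(t_k + 0.3, if (is.finite(next_bout_start)) {
    t[min(next_bout_start, length(t))]
  } else Inf)
  post <- which(t > t_k & t <= post_lim)
  if (length(post) < 5 || !is.finite(v_f)) {
    return(tibble(t_k_s = t_k, rho_k_mm = rho_k, v_f_mm_s = v_f, c_mm = c_mm,
                  u_mm_s = NA_real_, lambda_s = NA_real_,
                  fit_rms_mm = NA_real_, flag = "unfit"))
  }
  tt <- t[post] - t_k
  yy <- rho[post]
  ca <- cos(alpha_onset)
  best <- NULL
  starts <- lapply(c(0.02, 0.04, 0.08), function(lam0) {
    u0 <- if (abs(ca) > 0.05) {
      max((yy[length(yy)] - rho_k + v_f * tt[length(tt)]) / (lam0 * ca), 0.01)
    } else 1
    list(u0 = u0, lam0 = lam0)
  })
  # extra start away from u = 0, where the Jacobian in lambda degenerates
  starts <- c(starts, list(list(u0 = 5, lam0 = 0.04)))
  resid_fn <- function(par) {
    yy - rho_impulse_model(tt, rho_k, par[1], par[2], v_f, alpha_onset)
  }
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(u = st$u0, lambda = st$lam0), fn = resid_fn,
        lower = c(0, 0.004), upper = c(Inf, 0.5),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && all(is.finite(fit$par))) {
      rss <- fit$deviance
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(par = fit$par, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(tibble(t_k_s = t_k, rho_k_mm = rho_k, v_f_mm_s = v_f, c_mm = c_mm,
                  u_mm_s = NA_real_, lambda_s = NA_real_,
                  fit_rms_mm = NA_real_, flag = "no_converge"))
  }
  tibble(
    t_k_s = t_k, rho_k_mm = rho_k, v_f_mm_s = v_f, c_mm = c_mm,
    u_mm_s = unname(best$par["u"]), lambda_s = unname(best$par["lambda"]),
    fit_rms_mm = sqrt(best$rss / length(yy)), flag = ""
  )
}

#' Detect and fit all bouts of one track
#'
#' Runs the activity detector, tail-beat counter and kinematic fits over a
#' single track's contiguous segments (gaps split the analysis; fits operate
#' on observed samples only).
#'
#' @param track One track's pose tibble (columns `frame`, `t_s`, `rho_mm`,
#'   `alpha_rad`, `kappa_per_mm`; a `larva_id` column is carried through).
#' @param frame_rate Sampling rate, Hz.
#' @param threshold,min_duration Detector parameters ([detect_bouts()]).
#' @param beat_threshold Tail-beat threshold ([count_tail_beats()]).
#' @return A tibble of bout kinematics, one row per bout: `larva_id`, `k`,
#'   onset/offset angles, `t_k_s`, `rho_k_mm`, `v_f_mm_s`, `u_mm_s`,
#'   `lambda_s`, `n`, `tau_b_s`, `mean_abs_kappa_per_mm`, `fit_rms_mm`,
#'   `flag`, plus detector interval times.
#' @export
detect_track_bouts <- function(track, frame_rate, threshold = 5,
                               min_duration = 0.04, beat_threshold = 0.1) {
  track <- dplyr::arrange(as_tibble(track), .data$frame)
  id <- if ("larva_id" %in% names(track)) track$larva_id[1] else NA_integer_
  seg_id <- cumsum(c(1, diff(track$frame) > 1))
  out <- lapply(split(seq_len(nrow(track)), seg_id), function(rows) {
    seg <- track[rows, ]
    if (nrow(seg) < ceiling(0.4 * frame_rate)) return(NULL)
    act <- bout_activity(seg$kappa_per_mm, frame_rate)
    iv <- detect_bouts(act$activity, frame_rate, threshold, min_duration)
    if (nrow(iv) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(iv)), function(b) {
      one <- iv[b, ]
      beats <- count_tail_beats(seg$kappa_per_mm, one, frame_rate,
                                beat_threshold)
      nxt <- if (b < nrow(iv)) iv$start[b + 1] else Inf
      # body angle at the impulse start t_k (the detected interval begins a
      # few samples earlier because the activity windows are centered);
      # short circular means reject single-frame head-identity glitches
      ik <- one$start - 1 + which.min(seg$rho_mm[one$start:one$end])
      a_on <- circ_mean_window(seg$alpha_rad, ik, nrow(seg))
      a_off <- circ_mean_window(seg$alpha_rad, one$end, nrow(seg))
      kin <- fit_bout_kinematics(seg$t_s, seg$rho_mm, one,
                                 alpha_onset = a_on,
                                 next_bout_start = nxt,
                                 frame_rate = frame_rate)
      dplyr::mutate(
        kin,
        larva_id = id,
        alpha_onset_rad = a_on,
        alpha_offset_rad = a_off,
        n = beats$n, tau_b_s = beats$tau_b_s,
        mean_abs_kappa_per_mm = beats$mean_abs_kappa,
        t_start_s = seg$t_s[one$start], t_end_s = seg$t_s[one$end],
        flag = paste0(.data$flag, ifelse(beats$flag == "", "",
                                         paste0(";", beats$flag)))
      )
    })
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(res)
  res |>
    dplyr::arrange(.data$t_k_s) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::relocate("larva_id", "k")
}

#' Inter-bout series of one track
#'
#' Pairwise inter-bout periods `tau_k = t_{k+1} - t_k` and distances
#' `delta_k = rho_{k+1} - rho_k` from a time-ordered bout table.
#'
#' @param bouts Bout tibble of one track (needs `t_k_s`, `rho_k_mm`;
#'   `larva_id` carried through). An empty or single-bout input gives an
#'   empty series.
#' @return A tibble `larva_id`, `k`, `tau_s`, `delta_mm`, `rho_k_mm`.
#' @export
build_series <- function(bouts) {
  bouts <- dplyr::arrange(as_tibble(bouts), .data$t_k_s)
  if (nrow(bouts) < 2) {
    return(tibble(larva_id = integer(), k = integer(), tau_s = numeric(),
                  delta_mm = numeric(), rho_k_mm = numeric()))
  }
  tibble(
    larva_id = if ("larva_id" %in% names(bouts)) bouts$larva_id[-nrow(bouts)]
               else NA_integer_,
    k = seq_len(nrow(bouts) - 1),
    tau_s = diff(bouts$t_k_s),
    delta_mm = diff(bouts$rho_k_mm),
    rho_k_mm = bouts$rho_k_mm[-nrow(bouts)]
  )
}
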