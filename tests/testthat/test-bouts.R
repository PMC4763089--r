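test_that("activity is zero (flagged) on constant curvature and
           scale-invariant otherwise", {
  act0 <- bout_activity(rep(0.2, 300), 250)
  expect_true(all(act0$activity == 0))
  expect_true(all(act0$flag == "flat"))

  kap <- burst_trace(1000, 250, list(c(1.0, 1.2)))
  a1 <- bout_activity(kap, 250)$activity
  a2 <- bout_activity(5 * kap, 250)$activity
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("activity is high inside a burst and near 1 outside", {
  fr <- 250
  kap <- burst_trace(1500, fr, list(c(2.0, 2.2)), amplitude = 0.4,
                     noise_sd = 0.01)
  act <- bout_activity(kap, fr)$activity
  t <- (seq_len(1500) - 1) / fr
  inside <- t > 2.04 & t < 2.16
  outside <- t < 1.5 | t > 3.0
  expect_gt(min(act[inside]), 5)
  expect_lt(abs(median(act[outside]) - 1), 0.5)
})

test_that("bout detection honours threshold and minimum duration", {
  fr <- 250
  flat <- bout_activity(burst_trace(500, fr, list()), fr)$activity
  expect_equal(nrow(detect_bouts(flat, fr)), 0)

  one <- burst_trace(1250, fr, list(c(2.0, 2.2)))
  iv <- detect_bouts(bout_activity(one, fr)$activity, fr)
  expect_equal(nrow(iv), 1)
  expect_lt(iv$t_start_s, 2.02)
  expect_gt(iv$t_end_s, 2.15)

  # a 20 ms blip is rejected by the 40 ms minimum duration
  blip <- burst_trace(1250, fr, list(c(2.0, 2.02)))
  expect_equal(nrow(detect_bouts(bout_activity(blip, fr)$activity, fr)), 0)
})

test_that("tail beats: n and tau_b from a clean sinusoid; sub-threshold
           amplitude counts zero; constant offsets are ignored", {
  fr <- 250
  t <- seq(0, 1, by = 1 / fr)
  period <- 0.05
  kap <- ifelse(t >= 0.3 & t < 0.3 + 3 * period,
                0.3 * sin(2 * pi * (t - 0.3) / period), 0)
  iv <- list(start = which.min(abs(t - 0.3)),
             end = which.min(abs(t - (0.3 + 3 * period))))
  res <- count_tail_beats(kap, iv, fr)
  expect_equal(res$n, 3L)
  expect_equal(res$tau_b_s, period, tolerance = 1 / fr)

  res_small <- count_tail_beats(kap * (0.05 / 0.3), iv, fr)
  expect_equal(res_small$n, 0L)
  expect_equal(res_small$flag, "no_beats")

  res_off <- count_tail_beats(kap + 0.7, iv, fr)
  expect_equal(res_off$n, res$n)
  expect_equal(res_off$tau_b_s, res$tau_b_s)
})

test_that("detector is invariant to curvature sign flips and offsets", {
  fr <- 250
  kap <- burst_trace(1500, fr, list(c(1.0, 1.2), c(3.5, 3.7)))
  iv0 <- detect_bouts(bout_activity(kap, fr)$activity, fr)
  iv1 <- detect_bouts(bout_activity(-kap, fr)$activity, fr)
  iv2 <- detect_bouts(bout_activity(kap + 1.3, fr)$activity, fr)
  expect_equal(iv1, iv0)
  expect_equal(iv2, iv0)
})

test_that("noiseless impulse traces are recovered to machine precision and
           the u = 0 trace degenerates to pure drift", {
  tr <- impulse_trace(u = 20, lambda = 0.04, v_f = 1)
  k <- fit_bout_kinematics(tr$t, tr$rho, tr$interval, alpha_onset = 0,
                           frame_rate = 250)
  expect_lt(abs(k$u_mm_s - 20) / 20, 1e-6)
  expect_lt(abs(k$lambda_s - 0.04) / 0.04, 1e-6)
  expect_lt(abs(k$v_f_mm_s - 1) / 1, 1e-6)

  drift <- impulse_trace(u = 0, lambda = 0.04, v_f = 1)
  k0 <- fit_bout_kinematics(drift$t, drift$rho, drift$interval,
                            alpha_onset = 0, frame_rate = 250)
  expect_lt(k0$u_mm_s, 1e-6)
  expect_equal(k0$v_f_mm_s, 1, tolerance = 1e-9)
})

test_that("for v_f = 0 the fitted asymptotic displacement equals
           lambda * u * cos(alpha)", {
  alpha <- 0.5
  tr <- impulse_trace(u = 15, lambda = 0.05, v_f = 0, alpha = alpha)
  k <- fit_bout_kinematics(tr$t, tr$rho, tr$interval, alpha_onset = alpha,
                           frame_rate = 250)
  # closed-form limit of the impulse response as t -> Inf
  expect_equal(k$lambda_s * k$u_mm_s * cos(alpha),
               0.05 * 15 * cos(alpha), tolerance = 1e-6)
  # and it matches the observed plateau
  expect_equal(max(tr$rho) - tr$rho[tr$interval$start],
               0.05 * 15 * cos(alpha), tolerance = 1e-3)
})

test_that("too-short post windows are kept but flagged unfit", {
  tr <- impulse_trace(t_total = 0.11, t_on = 0.1)
  k <- fit_bout_kinematics(tr$t, tr$rho,
                           list(start = tr$interval$start,
                                end = length(tr$t) - 1),
                           alpha_onset = 0, frame_rate = 250)
  expect_equal(k$flag, "unfit")
  expect_true(is.na(k$u_mm_s))
})

test_that("inter-bout series follow the pairwise definitions", {
  b <- tibble::tibble(larva_id = 1L, t_k_s = c(1, 2, 4),
                      rho_k_mm = c(10, 9, 9))
  s <- build_series(b)
  expect_equal(s$tau_s, c(1, 2))
  expect_equal(s$delta_mm, c(-1, 0))
  expect_equal(nrow(build_series(b[1, ])), 0)
})

test_that("bouts detected on a generated session match the schedule", {
  cfg <- default_cfg()
  ss <- simulate_session(cfg, larva_model(), behavior_params(),
                         n_larvae = 1, duration = 10, seed = 21)
  tr <- dplyr::filter(ss$poses, larva_id == 1)
  set.seed(1)
  tr$kappa_per_mm <- tr$kappa_per_mm + rnorm(nrow(tr), 0, 0.01)
  tr$rho_mm <- tr$rho_mm + rnorm(nrow(tr), 0, 0.035)
  bouts <- detect_track_bouts(tr, frame_rate = cfg$frame_rate)
  truth <- dplyr::filter(ss$bouts, larva_id == 1)
  # most truth bouts overlap a detected interval (closely spaced exploration
  # bouts may merge into one detection)
  matched <- vapply(truth$t_k_s, function(tk) {
    any(bouts$t_start_s - 0.06 <= tk & tk <= bouts$t_end_s + 0.02)
  }, logical(1))
  expect_gt(mean(matched), 0.8)
  expect_lt(nrow(bouts), nrow(truth) * 1.3)
})
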