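test_that("circular variance anchors and invariances", {
  expect_equal(circular_variance(seq(0, 2 * pi, length.out = 9)[-9]), 1,
               tolerance = 1e-12)
  expect_equal(circular_variance(rep(0.7, 100)), 0, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, pi / 2)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(circular_variance(numeric(0)))
  # in [0, 1] and rotation-invariant for arbitrary samples
  set.seed(1)
  for (i in 1:20) {
    a <- runif(sample(1:40, 1), -pi, pi)
    v <- circular_variance(a)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(circular_variance(a + 1.3), v, tolerance = 1e-12)
  }
})

make_bouts <- function(id, t0, alphas_on, alphas_off, u = 10) {
  tibble::tibble(
    larva_id = id, k = seq_along(alphas_on),
    t_k_s = t0 + seq_along(alphas_on) - 1,
    rho_k_mm = 9, v_f_mm_s = 1,
    alpha_onset_rad = alphas_on, alpha_offset_rad = alphas_off,
    u_mm_s = u
  )
}

test_that("CSS labeling finds the first qualifying run", {
  # exploration-only: wide offsets -> no label
  b1 <- make_bouts(1, 0, runif(6, 2, 3), runif(6, 2, 3))
  l1 <- label_css(b1)
  expect_true(is.na(l1$onset_k))

  # aligned from bout 5 onward
  on <- c(runif(4, 2, 3), rep(0.1, 5))
  off <- c(runif(4, 2, 3), rep(0.2, 5))
  b2 <- make_bouts(2, 0, on, off)
  l2 <- label_css(b2)
  expect_equal(l2$onset_k, 5)
  expect_equal(l2$onset_t_s, b2$t_k_s[5])

  # run_length 1 labels the first counterflow bout
  b3 <- make_bouts(3, 0, c(2.5, 0.1, 2.5), c(2.5, 0.1, 2.5))
  expect_equal(label_css(b3, run_length = 1)$onset_k, 2)

  # an outward-impulse test: u cos(alpha_onset) must be positive
  b4 <- make_bouts(4, 0, rep(3, 5), rep(0.1, 5))   # facing the sink
  expect_true(is.na(label_css(b4)$onset_k))
})

test_that("aligned circular variance is high before and low after a
           programmed onset", {
  set.seed(2)
  bouts <- dplyr::bind_rows(lapply(1:24, function(id) {
    # pre-onset: onset angles uniform (pooled variance near 1); offset
    # angles misaligned (|alpha| > 60 deg) so no pre bout qualifies
    pre_on <- runif(6, -pi, pi)
    pre_off <- sample(c(-1, 1), 6, replace = TRUE) * runif(6, pi / 3, pi)
    post <- rnorm(6, 0, 0.1)
    make_bouts(id, 0, c(pre_on, post), c(pre_off, post))
  }))
  labels <- label_css(bouts)
  expect_true(all(labels$onset_k == 7))
  av <- aligned_circvar(bouts, labels, bin = 1, window = 6)
  pre_bins <- av$var_c[av$t_rel_s < 0 & !is.na(av$var_c)]
  post_bins <- av$var_c[av$t_rel_s > 0 & !is.na(av$var_c)]
  expect_gt(min(pre_bins), 0.6)
  expect_lt(max(post_bins), 0.2)
  expect_error(aligned_circvar(bouts, labels[0, ]), "no labeled")
})

test_that("kde integrates to one, is permutation invariant, and places modes
           at well-separated points", {
  set.seed(4)
  x <- rnorm(200, 3, 2)
  d <- kde(x, bandwidth = 0.5)
  expect_lt(abs(rheopipe:::trapz(d$x, d$density) - 1), 1e-6)
  d2 <- kde(sample(x), bandwidth = 0.5)
  expect_equal(d$density, d2$density, tolerance = 1e-12)

  # single point: a Gaussian centered there
  d1 <- kde(c(0, 0), bandwidth = 1)
  expect_lt(abs(d1$x[which.max(d1$density)]), 0.02)
  expect_equal(max(d1$density), stats::dnorm(0, 0, 1), tolerance = 1e-3)

  # two points +-5 sigma apart: two equal modes at the points
  dd <- kde(c(-5, 5), bandwidth = 1)
  peaks <- dd$x[order(dd$density, decreasing = TRUE)[1:2]]
  expect_equal(sort(round(abs(peaks))), c(5, 5))
  expect_error(kde(c(1, 2), bandwidth = 0), "bandwidth")
  expect_error(kde(1, bandwidth = 1), "2 samples")
})

test_that("KS statistic equals the exhaustive CDF-gap oracle; Welch handles
           unequal variances and rejects degenerate input", {
  brute_D <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(vapply(pts, function(p) {
      abs(mean(x <= p) - mean(y <= p))
    }, numeric(1)))
  }
  expect_equal(compare_distributions(1:5, 1:5)$statistic, 0)
  expect_equal(compare_distributions(rep(0, 5), rep(1, 5))$statistic, 1)
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(3:25, 1))
    y <- rnorm(sample(3:25, 1), sample(0:2, 1))
    expect_equal(compare_distributions(x, y)$statistic, brute_D(x, y),
                 tolerance = 1e-12)
  }
  w <- compare_distributions(rnorm(30), rnorm(30, 5), method = "welch")
  expect_lt(w$p_value, 1e-6)
  expect_equal(w$stars, "**")
  expect_error(compare_distributions(rep(1, 5), rep(2, 5), method = "welch"),
               "degenerate")
})

test_that("radial profile reflects programmed holding and operating points", {
  # perfect holding: delta identically 0
  s0 <- tibble::tibble(larva_id = 1, k = 1:50, tau_s = 1,
                       delta_mm = 0, rho_k_mm = runif(50, 2, 12))
  pr0 <- radial_profile(s0, breaks = seq(0, 14, 2))
  expect_true(all(pr0$delta_mean_mm[!is.na(pr0$delta_mean_mm)] == 0))

  # attraction/repulsion around rho* = 7: delta = 0.5 * (7 - rho)
  set.seed(6)
  rho <- runif(400, 2, 12)
  s1 <- tibble::tibble(larva_id = 1, k = seq_along(rho), tau_s = 1,
                       delta_mm = 0.5 * (7 - rho) + rnorm(400, 0, 0.1),
                       rho_k_mm = rho)
  pr1 <- radial_profile(s1, breaks = seq(0, 14, 1))
  sgn <- sign(pr1$delta_mean_mm[!is.na(pr1$delta_mean_mm)])
  mids <- pr1$rho_mid_mm[!is.na(pr1$delta_mean_mm)]
  crossing <- mids[which(diff(sgn) != 0)]
  expect_lte(abs(crossing - 7), 1)

  # single pair: SE masked
  pr2 <- radial_profile(s1[1, ], breaks = seq(0, 14, 1), n_min = 1)
  expect_equal(sum(!is.na(pr2$delta_mean_mm)), 1)
  expect_true(all(is.na(pr2$delta_se_mm)))
})

test_that("onset summary recovers a fixed trigger radius across flow rates
           and detects non-uniform onset radii", {
  cfg <- default_cfg()
  set.seed(7)
  rates <- c(150, 300, 450)
  bouts <- dplyr::bind_rows(lapply(seq_along(rates), function(g) {
    ids <- (g - 1) * 20 + 1:20
    dplyr::bind_rows(lapply(ids, function(id) {
      rho1 <- 8 + rnorm(1, 0, 0.2)
      b <- make_bouts(id, 0, rep(0.1, 4), rep(0.1, 4))
      b$rho_k_mm <- rho1
      b$v_f_mm_s <- flow_speed(rho1, flow_config(Q_v = rates[g]))
      b
    }))
  }))
  labels <- label_css(bouts)
  groups <- tibble::tibble(larva_id = unique(bouts$larva_id),
                           group = rep(rates, each = 20))
  os <- onset_summary(bouts, labels, group = groups, config = cfg, seed = 3)
  expect_equal(nrow(os$groups), 3)
  expect_true(all(abs(os$groups$rho1_mean_mm - 8) < 0.2))
  # v1 proportional to the flow rate at fixed rho*
  v1 <- os$groups$v1_mean_mm_s[order(os$groups$group)]
  expect_equal(v1[2] / v1[1], 2, tolerance = 0.05)
  expect_equal(v1[3] / v1[1], 3, tolerance = 0.05)
  # onsets concentrated at 8 mm differ from uniform FOV radii
  expect_lt(os$ks_uniform$p_value, 1e-6)
  expect_equal(tidy(os), os$groups)
})

test_that("egocentric density puts the sink ahead when facing it, behind
           when fleeing, and on a ring for uniform alpha", {
  cfg <- default_cfg()
  sink <- cfg$sink
  mk <- function(alpha, n = 400, rho = 6) {
    theta <- runif(n, -pi, pi)
    tibble::tibble(
      x_mm = sink[1] + rho * cos(theta),
      y_mm = sink[2] + rho * sin(theta),
      heading_rad = theta + alpha
    )
  }
  set.seed(8)
  facing <- egocentric_density(mk(pi), cfg)     # alpha = pi: facing the sink
  com_fwd <- sum(facing$forward_mm * facing$density) / sum(facing$density)
  expect_gt(com_fwd, 3)
  fleeing <- egocentric_density(mk(0), cfg)     # alpha = 0: sink behind
  com_fwd0 <- sum(fleeing$forward_mm * fleeing$density) / sum(fleeing$density)
  expect_lt(com_fwd0, -3)

  # uniform alpha at fixed rho: mass on a ring of radius rho
  unif <- mk(0, n = 2000)
  unif$heading_rad <- runif(2000, -pi, pi)
  ring <- egocentric_density(unif, cfg)
  r <- sqrt(ring$forward_mm^2 + ring$lateral_mm^2)
  mass_on_ring <- sum(ring$density[abs(r - 6) < 1]) / sum(ring$density)
  expect_gt(mass_on_ring, 0.95)
  # normalized: grid integral is 1
  expect_equal(sum(ring$density) * 0.5^2, 1, tolerance = 1e-9)
})
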