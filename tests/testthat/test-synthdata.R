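test_that("sessions are reproducible by seed and differ across seeds", {
  cfg <- default_cfg()
  lv <- larva_model()
  s1 <- simulate_session(cfg, lv, behavior_params(), n_larvae = 2,
                         duration = 3, seed = 5)
  s2 <- simulate_session(cfg, lv, behavior_params(), n_larvae = 2,
                         duration = 3, seed = 5)
  s3 <- simulate_session(cfg, lv, behavior_params(), n_larvae = 2,
                         duration = 3, seed = 6)
  expect_identical(s1$poses, s2$poses)
  expect_identical(s1$bouts, s2$bouts)
  expect_false(identical(s1$poses, s3$poses))
})

test_that("zero bout rate gives purely passive drift toward the sink", {
  cfg <- default_cfg()
  ss <- simulate_session(cfg, larva_model(),
                         behavior_params(explore_rate = 0),
                         n_larvae = 1, duration = 4, seed = 2)
  expect_equal(nrow(ss$bouts), 0)
  rho <- ss$poses$rho_mm
  expect_true(all(diff(rho) <= 1e-9))
  expect_true(all(ss$poses$phase == "exploration"))
})

test_that("passive drift conserves theta exactly when alpha starts at 0", {
  cfg <- default_cfg()
  init <- tibble::tibble(x_mm = 16, y_mm = 9)        # east of the sink
  init$heading_rad <- 0                              # pointing outward
  ss <- simulate_session(cfg, larva_model(),
                         behavior_params(explore_rate = 0),
                         n_larvae = 1, duration = 3, seed = 3, init = init)
  expect_equal(ss$poses$theta_rad, rep(0, nrow(ss$poses)), tolerance = 1e-12)
  expect_equal(ss$poses$alpha_rad, rep(0, nrow(ss$poses)), tolerance = 1e-12)
})

test_that("the phase label flips exactly once, at the first bout after the
           trigger crossing", {
  cfg <- default_cfg()
  pp <- behavior_params(trigger_rho = 8)
  ss <- simulate_session(cfg, larva_model(), pp, n_larvae = 3,
                         duration = 12, seed = 11)
  for (id in unique(ss$poses$larva_id)) {
    p <- dplyr::filter(ss$poses, larva_id == id)
    r <- rle(p$phase)
    expect_lte(length(r$values), 2)
    expect_equal(r$values[1], "exploration")
    if (length(r$values) == 2) {
      expect_equal(r$values[2], "css")
      onset_frame <- r$lengths[1] + 1
      b <- dplyr::filter(ss$bouts, larva_id == id, phase == "css")
      expect_equal(min(b$t_k_s), p$t_s[onset_frame])
      # the onset bout is the first bout after the larva crossed inward
      crossed <- which(p$rho_mm <= pp$trigger_rho)[1]
      expect_gte(onset_frame, crossed)
    }
  }
})

test_that("initial positions outside the field of view are rejected", {
  cfg <- default_cfg()
  expect_error(
    simulate_session(cfg, larva_model(), behavior_params(), seed = 1,
                     duration = 1,
                     init = tibble::tibble(x_mm = 30, y_mm = 5)),
    "outside"
  )
})

test_that("rendered straight rod matches its programmed orientation and
           area exceeds the size-filter scale", {
  cfg <- default_cfg()
  lv <- larva_model()
  fr <- render_pose(11, 9, 30 * pi / 180, 0, lv, cfg)
  blobs <- segment_frame(fr, blank_bg(cfg), segmentation_params(), cfg)
  expect_equal(nrow(blobs), 1)
  expect_gt(blobs$area_px[1], 500)
  ell <- equivalent_ellipse(blobs$pixels[[1]])
  # orientation is axial: compare modulo pi
  d <- abs(ell$orientation - 30 * pi / 180) %% pi
  expect_lt(min(d, pi - d) * 180 / pi, 1)
})

test_that("renderer refuses a body that closes on itself", {
  cfg <- default_cfg()
  expect_error(render_pose(11, 9, 0, pi / 4 + 0.01, larva_model(), cfg),
               "close")
})

test_that("no larvae and no noise renders pure background; mirrored poses
           render mirror images", {
  cfg <- small_cfg()
  lv <- larva_model()
  empty <- simulate_session(cfg, lv, behavior_params(explore_rate = 0),
                            n_larvae = 1, duration = 0.1, seed = 1)
  empty$poses <- empty$poses[0, ]
  fr <- render_frames(empty, larva = lv, config = cfg,
                      noise = render_noise(0, 0), frames = 1:2)
  expect_true(all(vapply(fr$frames, function(m) all(m == 0), logical(1))))

  # mirror about the horizontal mid-line of the fov: y -> H - y,
  # heading -> -heading, kappa -> -kappa (pixel grid chosen to close exactly)
  cfgm <- flow_config(fov = c(0, 0, 10, 8), pixel_size = 0.04)
  a <- render_pose(5, 3, 0.6, 0.4, lv, cfgm)
  b <- render_pose(5, 8 - 3, -0.6, -0.4, lv, cfgm)
  expect_equal(a, b[nrow(b):1, ], tolerance = 1e-12)
})

test_that("posture round trip on noiseless renders: position within 1 px,
           heading within 2 degrees (straight), kappa within 10%", {
  cfg <- default_cfg()
  lv <- larva_model()
  cases <- expand.grid(phi = c(0, 0.9, 2.2, -2.8),
                       kappa = c(0, 0.2, -0.35, 0.5))
  for (i in seq_len(nrow(cases))) {
    phi <- cases$phi[i]; kap <- cases$kappa[i]
    p <- render_and_pose(13, 10, phi, kap, lv, cfg)
    expect_lt(sqrt((p$x_mm - 13)^2 + (p$y_mm - 10)^2), cfg$pixel_size)
    if (kap == 0) {
      dh <- abs(wrapped_diff(p$heading_rad, phi)) * 180 / pi
      expect_lt(dh, 2)
      expect_equal(p$kappa_per_mm, 0)
    } else {
      expect_lt(abs(abs(p$kappa_per_mm) - abs(kap)) / abs(kap), 0.1)
      expect_equal(sign(p$kappa_per_mm), sign(kap))
    }
  }
})
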