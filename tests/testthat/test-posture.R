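test_that("equivalent ellipse recovers an analytic filled ellipse", {
  px <- 0.035
  a <- 20 * px; b <- 5 * px
  pix <- ellipse_pixels(3, 4, a, b, 30 * pi / 180, pixel_size = px)
  ell <- equivalent_ellipse(pix)
  expect_lt(abs(ell$semi_major - a) / a, 0.02)
  expect_lt(abs(ell$semi_minor - b) / b, 0.02)
  d <- abs(ell$orientation - 30 * pi / 180) %% pi
  expect_lt(min(d, pi - d) * 180 / pi, 1)
  expect_equal(ell$center, c(3, 4), tolerance = 1e-3)
  expect_false(ell$isotropic)
})

test_that("a circular disk is isotropic and flagged", {
  pix <- ellipse_pixels(0, 0, 0.5, 0.5, 0)
  ell <- equivalent_ellipse(pix)
  expect_lt((ell$semi_major - ell$semi_minor) / ell$semi_major, 0.02)
  expect_true(ell$isotropic)
})

test_that("rotating a blob by 90 degrees rotates the orientation, axes
           unchanged", {
  pix <- ellipse_pixels(0, 0, 0.7, 0.2, 0.4)
  rot <- pix
  rot$x_mm <- -pix$y_mm
  rot$y_mm <- pix$x_mm
  e1 <- equivalent_ellipse(pix)
  e2 <- equivalent_ellipse(rot)
  expect_equal(e2$semi_major, e1$semi_major, tolerance = 1e-9)
  expect_equal(e2$semi_minor, e1$semi_minor, tolerance = 1e-9)
  d <- abs(e2$orientation - (e1$orientation + pi / 2)) %% pi
  expect_lt(min(d, pi - d), 1e-6)
})

test_that("degenerate blobs are rejected", {
  line <- tibble::tibble(x_mm = seq(0, 1, by = 0.035), y_mm = 0,
                         intensity = 1)
  expect_error(equivalent_ellipse(line), "degenerate")
  expect_error(equivalent_ellipse(line[1:3, ]), "small")
})

test_that("BSP split partitions the blob; symmetric rods split evenly; the
           head half of a rendered larva is heavier", {
  # symmetric uniform rod
  rod <- ellipse_pixels(0, 0, 1.5, 0.2, 0.7)
  halves <- decompose_bsp(rod)
  expect_lte(abs(nrow(halves$half_a) - nrow(halves$half_b)),
             nrow(rod) * 0.02)
  expect_equal(nrow(halves$half_a) + nrow(halves$half_b), nrow(rod))

  # rendered larva: wider head half has strictly larger area, and the head
  # direction points at the true heading side
  cfg <- default_cfg()
  lv <- larva_model()
  for (kap in c(0, 0.3)) {
    fr <- render_pose(11, 9, 0.5, kap, lv, cfg)
    blobs <- segment_frame(fr, blank_bg(cfg), segmentation_params(), cfg)
    h <- decompose_bsp(blobs$pixels[[1]])
    ht <- identify_head(h$half_a, h$half_b)
    expect_gt(nrow(ht$head), nrow(ht$tail))
    # union is a partition of the blob
    expect_equal(nrow(ht$head) + nrow(ht$tail), nrow(blobs$pixels[[1]]))
    head_ctr <- c(mean(ht$head$x_mm), mean(ht$head$y_mm))
    expect_gt(sum((head_ctr - c(11, 9)) * unit_vec_test(0.5)), 0)
  }
})

test_that("head identification uses history when available and a
           deterministic tie-break otherwise", {
  half_a <- ellipse_pixels(1, 0, 0.3, 0.2, 0)
  half_b <- ellipse_pixels(-1, 0, 0.3, 0.2, 0)   # same shape, equal areas
  prev <- tibble::tibble(head_x_mm = -0.9, head_y_mm = 0)
  ht <- identify_head(half_a, half_b, prev)
  expect_lt(mean(ht$head$x_mm), 0)    # continuity decides
  expect_false(ht$ambiguous)
  ht2 <- identify_head(half_a, half_b)
  expect_lt(mean(ht2$head$x_mm), 0)   # smaller-x tie-break
  expect_true(ht2$ambiguous)
})

test_that("alpha follows the outward-radial convention", {
  cfg <- default_cfg()
  lv <- larva_model()
  sink <- cfg$sink
  # larva east of the sink pointing east = away from the sink -> alpha = 0
  p_away <- render_and_pose(sink[1] + 5, sink[2], 0, 0, lv, cfg)
  expect_lt(abs(p_away$alpha_rad) * 180 / pi, 2)
  # pointing at the sink -> alpha = pi
  p_toward <- render_and_pose(sink[1] + 5, sink[2], pi, 0, lv, cfg)
  expect_lt(abs(abs(p_toward$alpha_rad) - pi) * 180 / pi, 2)
  # 30 degrees off the outward radial
  p30 <- render_and_pose(sink[1] + 5, sink[2], 30 * pi / 180, 0, lv, cfg)
  expect_equal(p30$alpha_rad * 180 / pi, 30, tolerance = 2)
})

test_that("signed curvature: straight rod 0, rendered arcs within 10%,
           mirrored poses flip the sign", {
  cfg <- default_cfg()
  lv <- larva_model()
  p0 <- render_and_pose(11, 9, 0.8, 0, lv, cfg)
  expect_equal(p0$kappa_per_mm, 0)
  for (R in c(1.5, 2, 3)) {
    p <- render_and_pose(11, 9, 0.8, 1 / R, lv, cfg)
    expect_lt(abs(abs(p$kappa_per_mm) - 1 / R) * R, 0.1)
    m <- render_and_pose(11, 9, 0.8, -1 / R, lv, cfg)
    expect_equal(sign(m$kappa_per_mm), -sign(p$kappa_per_mm))
    expect_equal(abs(m$kappa_per_mm), abs(p$kappa_per_mm), tolerance = 0.05)
  }
})

test_that("rotation about the sink preserves rho, alpha, kappa and shifts
           theta", {
  cfg <- default_cfg()
  lv <- larva_model()
  rot <- 1.1
  base <- list(rho = 5, theta = 0.3, alpha = 0.6, kappa = 0.3)
  mk <- function(theta) {
    render_and_pose(cfg$sink[1] + base$rho * cos(theta),
                    cfg$sink[2] + base$rho * sin(theta),
                    theta + base$alpha, base$kappa, lv, cfg)
  }
  p1 <- mk(base$theta)
  p2 <- mk(base$theta + rot)
  expect_equal(p2$rho_mm, p1$rho_mm, tolerance = 0.02)
  expect_lt(abs(wrapped_diff(p2$theta_rad, p1$theta_rad + rot)), 0.02)
  expect_lt(abs(wrapped_diff(p2$alpha_rad, p1$alpha_rad)), 0.03)
  expect_equal(p2$kappa_per_mm, p1$kappa_per_mm, tolerance = 0.05)
})

test_that("kappa estimates are stable under finer pixel sampling", {
  lv <- larva_model()
  cfg1 <- flow_config(fov = c(0, 0, 12, 12), pixel_size = 0.035)
  cfg2 <- flow_config(fov = c(0, 0, 12, 12), pixel_size = 0.0175)
  p1 <- render_and_pose(6, 6, 0.8, 0.4, lv, cfg1)
  p2 <- render_and_pose(6, 6, 0.8, 0.4, lv, cfg2)
  expect_lt(abs(p1$kappa_per_mm - p2$kappa_per_mm) / abs(p1$kappa_per_mm),
            0.05)
})
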