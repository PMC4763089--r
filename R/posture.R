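# Posture estimation from image moments.
#
# The body angle alpha is measured from the OUTWARD radial direction (from
# the suction point through the larva) to the resolved head direction,
# wrapped to (-pi, pi]; alpha = 0 is perfect counterflow orientation. This
# convention is anchored by the bout impulse model, in which a bout of
# impulse u at angle alpha displaces the larva radially by +lambda u
# cos(alpha): a counterflow bout must increase rho.

#' Equivalent ellipse of a blob from image moments
#'
#' The ellipse with the same intensity-weighted zeroth, first and second
#' central moments as the blob: center = weighted centroid, axes and
#' orientation from the eigen-decomposition of the second-moment matrix
#' (semi-axes `2 * sqrt(eigenvalue)`).
#'
#' @param pixels A data frame of blob pixels with columns `x_mm`, `y_mm` and
#'   `intensity` (as in the `pixels` list-column of [segment_frame()]).
#' @return A list of class `equiv_ellipse`: `center` (mm), `semi_major`,
#'   `semi_minor` (mm), `orientation` (axial, in (-pi/2, pi/2]),
#'   `isotropic` (TRUE when the axes are equal within 2%, in which case the
#'   orientation is unconstrained).
#' @export
equivalent_ellipse <- function(pixels) {
  if (nrow(pixels) < 5) abort("blob too small for moment analysis (< 5 px).")
  w <- pixels$intensity
  m00 <- sum(w)
  cx <- sum(pixels$x_mm * w) / m00
  cy <- sum(pixels$y_mm * w) / m00
  dx <- pixels$x_mm - cx
  dy <- pixels$y_mm - cy
  mu20 <- sum(dx * dx * w) / m00
  mu02 <- sum(dy * dy * w) / m00
  mu11 <- sum(dx * dy * w) / m00
  e <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)
  if (e$values[1] <= 0 || e$values[2] <= 1e-12) {
    abort("degenerate blob: zero variance along an axis.")
  }
  a <- 2 * sqrt(e$values[1])
  b <- 2 * sqrt(e$values[2])
  v <- e$vectors[, 1]
  orient <- atan2(v[2], v[1])
  if (orient <= -pi / 2) orient <- orient + pi
  if (orient > pi / 2) orient <- orient - pi
  structure(
    list(center = c(cx, cy), semi_major = a, semi_minor = b,
         orientation = orient, isotropic = (a - b) / a < 0.02),
    class = "equiv_ellipse"
  )
}

#' Level-1 BSP decomposition of a blob
#'
#' Splits the blob by the line through the whole-blob (intensity-weighted)
#' centroid perpendicular to the whole-blob major axis, giving the two halves
#' whose equivalent ellipses describe head and tail. Pixels exactly on the
#' split plane go to half A (the positive side along the major axis).
#'
#' @param pixels Blob pixel data frame (columns `x_mm`, `y_mm`, `intensity`).
#' @return A list with `half_a` and `half_b` (pixel data frames; the split is
#'   a partition of the input) and `axis` (the whole-blob major-axis
#'   direction, axial).
#' @export
decompose_bsp <- function(pixels) {
  ell <- equivalent_ellipse(pixels)
  u <- unit_vec(ell$orientation)
  proj <- (pixels$x_mm - ell$center[1]) * u[1] +
    (pixels$y_mm - ell$center[2]) * u[2]
  half_a <- pixels[proj >= 0, , drop = FALSE]
  half_b <- pixels[proj < 0, , drop = FALSE]
  if (nrow(half_a) == 0 || nrow(half_b) == 0) {
    abort("degenerate BSP split: one half is empty.")
  }
  list(half_a = half_a, half_b = half_b, axis = ell$orientation)
}

#' Identify the head half of a decomposed blob
#'
#' The head is the heavier (larger-area) half whenever the areas differ
#' decisively (relative difference > `margin`); otherwise, with a previous
#' pose available, the head is the half whose centroid is nearer the
#' previous head center. Relying on continuity alone would let a single
#' mis-assignment propagate indefinitely (the rule is self-consistent), so
#' the anatomical evidence takes precedence when it is clear. Exact area
#' ties without history are broken toward the half with the smaller x
#' centroid and flagged ambiguous.
#'
#' @param half_a,half_b Pixel data frames from [decompose_bsp()].
#' @param previous_pose Optional previous `pose` row (needs `head_x_mm`,
#'   `head_y_mm`).
#' @param margin Relative area difference above which the heavier half is
#'   taken as the head regardless of history.
#' @return List with `head`, `tail` (pixel data frames) and `ambiguous`.
#' @export
identify_head <- function(half_a, half_b, previous_pose = NULL,
                          margin = 0.15) {
  ca <- c(mean(half_a$x_mm), mean(half_a$y_mm))
  cb <- c(mean(half_b$x_mm), mean(half_b$y_mm))
  na <- nrow(half_a); nb <- nrow(half_b)
  ambiguous <- FALSE
  has_prev <- !is.null(previous_pose) &&
    all(c("head_x_mm", "head_y_mm") %in% names(previous_pose))
  if (abs(na - nb) / max(na, nb) > margin) {
    a_first <- na > nb
  } else if (has_prev) {
    ph <- c(previous_pose$head_x_mm[1], previous_pose$head_y_mm[1])
    a_first <- sum((ca - ph)^2) <= sum((cb - ph)^2)
  } else if (na != nb) {
    a_first <- na > nb
  } else {
    a_first <- ca[1] < cb[1]
    ambiguous <- TRUE
  }
  if (a_first) {
    list(head = half_a, tail = half_b, ambiguous = ambiguous)
  } else {
    list(head = half_b, tail = half_a, ambiguous = ambiguous)
  }
}

#' Signed body curvature from the head and tail ellipses
#'
#' The center of curvature is the intersection of the two ellipses' minor
#' axes; the radius of curvature R is the mean distance from that center to
#' all blob pixels, and `kappa = +/- 1/R`, positive when the center lies on
#' the right-hand side of the resolved head direction. Near-parallel minor
#' axes (within `eps_angle`) give kappa = 0 (straight body).
#'
#' @param head_ell,tail_ell `equiv_ellipse` objects of the two halves.
#' @param pixels Whole-blob pixel data frame.
#' @param head_dir Resolved head direction, rad.
#' @param eps_angle Parallelism guard, rad (default 0.5 degrees).
#' @param kappa_cap Curvature magnitude cap, 1/mm.
#' @return Signed curvature, 1/mm.
#' @export
signed_curvature <- function(head_ell, tail_ell, pixels, head_dir,
                             eps_angle = 0.5 * pi / 180, kappa_cap = 2) {
  u1 <- right_normal(head_ell$orientation)  # minor-axis directions
  u2 <- right_normal(tail_ell$orientation)
  sin_between <- abs(cross2(u1[1], u1[2], u2[1], u2[2]))
  if (sin_between < sin(eps_angle)) return(0)
  # solve p1 + t1 u1 = p2 + t2 u2
  rhs <- tail_ell$center - head_ell$center
  A <- cbind(u1, -u2)
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) return(0)
  cc <- head_ell$center + sol[1] * u1
  R <- mean(sqrt((pixels$x_mm - cc[1])^2 + (pixels$y_mm - cc[2])^2))
  if (R <= 0) return(0)
  kap <- 1 / R
  ctr <- c(mean(pixels$x_mm), mean(pixels$y_mm))
  v <- cc - ctr
  on_right <- sum(v * right_normal(head_dir)) > 0
  kap <- if (on_right) kap else -kap
  sign(kap) * min(abs(kap), kappa_cap)
}

#' Full pose of one blob
#'
#' Combines the moment analysis: whole-blob polar coordinates about the
#' suction point, head/tail split, resolved head direction, body angle alpha
#' (from the outward radial direction, in (-pi, pi]) and signed curvature.
#'
#' @param blob One row of the [segment_frame()] table (or a list with a
#'   `pixels` data frame).
#' @param config A [flow_config()] (suction-point location).
#' @param previous_pose Optional previous pose row of the same larva, used to
#'   disambiguate the head.
#' @param t Time stamp, s.
#' @param eps_angle,kappa_cap Passed to [signed_curvature()].
#' @return A one-row tibble: `t_s`, `x_mm`, `y_mm`, `rho_mm`, `theta_rad`,
#'   `alpha_rad`, `kappa_per_mm`, `heading_rad`, `head_x_mm`, `head_y_mm`,
#'   ellipse axes of both halves, `ambiguous_head`, `flag`.
#' @export
pose_from_blob <- function(blob, config, previous_pose = NULL, t = NA_real_,
                           eps_angle = 0.5 * pi / 180, kappa_cap = 2) {
  pixels <- if (is.data.frame(blob)) blob$pixels[[1]] else blob$pixels
  halves <- decompose_bsp(pixels)
  ht <- identify_head(halves$half_a, halves$half_b, previous_pose)
  head_ell <- equivalent_ellipse(ht$head)
  tail_ell <- equivalent_ellipse(ht$tail)

  # binarized-body centroid (see segment_frame): robust to the smoothing's
  # width-dependent attenuation of the tail
  ctr <- c(mean(pixels$x_mm), mean(pixels$y_mm))
  d <- ctr - config$sink
  rho <- sqrt(sum(d^2))
  if (rho < 1e-9) abort("blob centroid coincides with the suction point.")
  theta <- atan2(d[2], d[1])

  # resolve the head ellipse's (axial) major axis to point outward from the
  # split plane through the head half's centroid
  axis_dir <- unit_vec(head_ell$orientation)
  to_head <- head_ell$center - ctr
  heading <- if (sum(axis_dir * to_head) >= 0) {
    head_ell$orientation
  } else {
    wrap_angle(head_ell$orientation + pi)
  }
  alpha <- wrap_angle(heading - theta)
  kap <- signed_curvature(head_ell, tail_ell, pixels, heading,
                          eps_angle = eps_angle, kappa_cap = kappa_cap)
  flag <- if (abs(kap) >= kappa_cap) "kappa_capped" else ""
  # new_tibble: this runs once per blob per frame, tibble()'s validation is
  # the dominant cost at that rate
  tibble::new_tibble(list(
    t_s = t, x_mm = ctr[1], y_mm = ctr[2], rho_mm = rho, theta_rad = theta,
    alpha_rad = alpha, kappa_per_mm = kap, heading_rad = heading,
    head_x_mm = head_ell$center[1], head_y_mm = head_ell$center[2],
    head_major_mm = head_ell$semi_major, head_minor_mm = head_ell$semi_minor,
    tail_major_mm = tail_ell$semi_major, tail_minor_mm = tail_ell$semi_minor,
    ambiguous_head = ht$ambiguous, flag = flag
  ), nrow = 1L)
}

#' Extract poses for all blobs of one frame
#'
#' @param blobs A [segment_frame()] table.
#' @param config A [flow_config()].
#' @param previous_poses Optional pose table of the previous frame; each blob
#'   is matched to the nearest previous pose (within `match_dist` mm) to
#'   stabilize head identification over time.
#' @param t Time stamp, s.
#' @param match_dist Matching distance for the history hint, mm.
#' @return A tibble of poses (one row per blob, with `blob_id`).
#' @export
extract_poses <- function(blobs, config, previous_poses = NULL, t = NA_real_,
                          match_dist = 3.5) {
  if (nrow(blobs) == 0) {
    out <- pose_from_blob_prototype()
    out$blob_id <- integer()
    return(out)
  }
  rows <- lapply(seq_len(nrow(blobs)), function(i) {
    prev <- NULL
    if (!is.null(previous_poses) && nrow(previous_poses) > 0) {
      dd <- sqrt((previous_poses$x_mm - blobs$cx_mm[i])^2 +
                 (previous_poses$y_mm - blobs$cy_mm[i])^2)
      j <- which.min(dd)
      if (dd[j] <= match_dist) prev <- previous_poses[j, ]
    }
    p <- pose_from_blob(blobs[i, ], config, previous_pose = prev, t = t)
    p$blob_id <- blobs$blob_id[i]
    p
  })
  dplyr::bind_rows(rows)
}

pose_from_blob_prototype <- function() {
  tibble(
    t_s = numeric(), x_mm = numeric(), y_mm = numeric(), rho_mm = numeric(),
    theta_rad = numeric(), alpha_rad = numeric(), kappa_per_mm = numeric(),
    heading_rad = numeric(), head_x_mm = numeric(), head_y_mm = numeric(),
    head_major_mm = numeric(), head_minor_mm = numeric(),
    tail_major_mm = numeric(), tail_minor_mm = numeric(),
    ambiguous_head = logical(), flag = character()
  )
}
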