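# Rendering of synthetic frames: each larva is an intensity stamp along a
# constant-curvature midline with the model's half-width profile, bright on a
# dark background. The ground-truth position is the body's area centroid; the
# midline placement is derived from it so that segmentation centroids are
# directly comparable to the truth.

# local (unrotated-frame) area centroid of the bent body relative to the
# midline midpoint, used to place the midline so that the stamp's centroid
# lands on the requested position
body_centroid_offset <- function(larva, phi, kappa) {
  s <- seq(-larva$L / 2, larva$L / 2, length.out = 101)
  w <- larva_halfwidth(larva, s / larva$L + 0.5)
  p <- arc_points(c(0, 0), phi, kappa, s)
  c(sum(p[, 1] * w), sum(p[, 2] * w)) / sum(w)
}

#' Render one larva pose into a frame matrix
#'
#' Draws a bright bent-rod larva (midline = circular arc of the pose's
#' curvature, width per the model's profile, 1-pixel anti-aliased edge) onto
#' `canvas` (or a new zero background). Pixel (r, c) has its center at
#' `x = (c - 0.5) * pixel_size`, `y = (r - 0.5) * pixel_size`.
#'
#' @param x_mm,y_mm Position of the body's area centroid, mm.
#' @param heading_rad Heading (tangent direction at the midline midpoint,
#'   pointing toward the head), rad.
#' @param kappa_per_mm Signed body curvature, 1/mm (positive: center of
#'   curvature on the right of the heading). `|kappa| * L` must be < pi.
#' @param larva A [larva_model()].
#' @param config A [flow_config()] (field of view and pixel size).
#' @param canvas Optional existing frame matrix to draw onto.
#' @return A numeric matrix (rows x cols, intensities in [0, 1]).
#' @export
render_pose <- function(x_mm, y_mm, heading_rad, kappa_per_mm, larva, config,
                        canvas = NULL) {
  px <- config$pixel_size
  nr <- round(config$fov[4] / px)
  nc <- round(config$fov[3] / px)
  if (is.null(canvas)) canvas <- matrix(0, nr, nc)
  if (abs(kappa_per_mm) * larva$L >= pi) {
    abort("|kappa| * L >= pi: the body would close on itself.")
  }
  L <- larva$L
  pos <- c(x_mm - config$fov[1], y_mm - config$fov[2])
  p_c <- pos - body_centroid_offset(larva, heading_rad, kappa_per_mm)
  w_max <- max(larva$width_profile$halfwidth)

  # bounding box of the midline plus width and anti-alias margin
  s_ref <- seq(-L / 2, L / 2, length.out = 41)
  pts <- arc_points(p_c, heading_rad, kappa_per_mm, s_ref)
  margin <- w_max + 3 * px
  c0 <- max(1L, floor((min(pts[, 1]) - margin) / px) + 1L)
  c1 <- min(nc, ceiling((max(pts[, 1]) + margin) / px))
  r0 <- max(1L, floor((min(pts[, 2]) - margin) / px) + 1L)
  r1 <- min(nr, ceiling((max(pts[, 2]) + margin) / px))
  if (c1 < c0 || r1 < r0) return(canvas)

  cols <- c0:c1
  rows <- r0:r1
  gx <- (rep(cols, each = length(rows)) - 0.5) * px
  gy <- (rep(rows, times = length(cols)) - 0.5) * px

  t_hat <- unit_vec(heading_rad)
  if (abs(kappa_per_mm) < 1e-9) {
    vx <- gx - p_c[1]; vy <- gy - p_c[2]
    s_x <- vx * t_hat[1] + vy * t_hat[2]
    d_perp <- abs(vx * t_hat[2] - vy * t_hat[1])
    s_cl <- pmin(pmax(s_x, -L / 2), L / 2)
    dist <- ifelse(abs(s_x) <= L / 2, d_perp,
                   sqrt((s_x - s_cl)^2 + d_perp^2))
  } else {
    kap <- kappa_per_mm
    cc <- p_c + right_normal(heading_rad) / kap
    v0 <- p_c - cc
    vx <- gx - cc[1]; vy <- gy - cc[2]
    rad <- sqrt(vx^2 + vy^2)
    ang <- atan2(v0[1] * vy - v0[2] * vx, v0[1] * vx + v0[2] * vy)
    s_x <- -ang / kap
    s_cl <- pmin(pmax(s_x, -L / 2), L / 2)
    inside <- abs(s_x) <= L / 2
    dist <- abs(rad - 1 / abs(kap))
    if (any(!inside)) {
      ends <- arc_points(p_c, heading_rad, kap, c(-L / 2, L / 2))
      e <- ifelse(s_cl[!inside] > 0, 2L, 1L)
      dist[!inside] <- sqrt((gx[!inside] - ends[e, 1])^2 +
                            (gy[!inside] - ends[e, 2])^2)
    }
  }
  w <- larva_halfwidth(larva, s_cl / L + 0.5)
  val <- larva$intensity * pmin(pmax((w - dist) / px + 0.5, 0), 1)
  patch <- matrix(val, nrow = length(rows), ncol = length(cols))
  canvas[rows, cols] <- pmax(canvas[rows, cols], patch)
  canvas
}

#' Render frames of a synthetic session
#'
#' Renders each larva of the session's per-frame pose table as a bright
#' bent rod on a dark background, with additive Gaussian intensity noise and
#' sub-pixel positional jitter. Noise is drawn from a per-frame stream derived
#' from `seed` and the frame index, so rendering a subset of frames gives the
#' same images as rendering the full stack (the renderer can be streamed).
#'
#' @param session A [simulate_session()] result (or any list with a `poses`
#'   tibble carrying `frame`, `t_s`, `larva_id`, `x_mm`, `y_mm`,
#'   `heading_rad`, `kappa_per_mm`).
#' @param larva,config Override the session's larva model / flow config.
#' @param noise A [render_noise()].
#' @param seed Integer seed for the noise streams (required unless both noise
#'   amplitudes are zero).
#' @param frames Optional integer vector of frame indices to render (default
#'   all).
#' @param out_of_view `"error"` (default) to reject poses outside the field
#'   of view, or `"skip"` to leave them unrendered (the larva has left the
#'   imaged region).
#' @return An object of class `rheo_frames`: list with `frames` (list of
#'   matrices), `meta` (tibble frame, t_s) and `config`.
#' @export
render_frames <- function(session, larva = session$larva,
                          config = session$config, noise = render_noise(),
                          seed = NULL, frames = NULL,
                          out_of_view = c("error", "skip")) {
  out_of_view <- match.arg(out_of_view)
  poses <- session$poses
  if (is.null(frames)) frames <- sort(unique(poses$frame))
  needs_rng <- noise$intensity_sigma > 0 || noise$pos_jitter > 0
  if (needs_rng && is.null(seed)) abort("`seed` is required when noise > 0.")
  px <- config$pixel_size
  nr <- round(config$fov[4] / px)
  nc <- round(config$fov[3] / px)

  fov <- config$fov
  in_fov <- poses$x_mm >= fov[1] & poses$x_mm <= fov[1] + fov[3] &
    poses$y_mm >= fov[2] & poses$y_mm <= fov[2] + fov[4]
  if (any(!in_fov)) {
    if (out_of_view == "error") {
      abort("poses must lie inside the field of view.")
    }
    poses <- poses[in_fov, , drop = FALSE]
  }

  by_frame <- split(poses, poses$frame)
  t_of <- vapply(split(poses$t_s, poses$frame), `[`, numeric(1), 1)

  out <- lapply(frames, function(f) {
    fr <- matrix(0, nr, nc)
    pf <- by_frame[[as.character(f)]]
    if (!is.null(pf) && nrow(pf) > 0) {
      jit <- if (noise$pos_jitter > 0) {
        with_stream(seed, "jitter", f,
                    code = matrix(rnorm(2 * nrow(pf), 0, noise$pos_jitter),
                                  ncol = 2))
      } else {
        matrix(0, nrow(pf), 2)
      }
      for (j in seq_len(nrow(pf))) {
        fr <- render_pose(pf$x_mm[j] + jit[j, 1], pf$y_mm[j] + jit[j, 2],
                          pf$heading_rad[j], pf$kappa_per_mm[j],
                          larva, config, canvas = fr)
      }
    }
    if (noise$intensity_sigma > 0) {
      fr <- fr + with_stream(seed, "noise", f,
                             code = matrix(rnorm(nr * nc, 0,
                                                 noise$intensity_sigma),
                                           nr, nc))
      fr[fr < 0] <- 0
      fr[fr > 1] <- 1
    }
    fr
  })
  structure(
    list(frames = out,
         meta = tibble(frame = frames,
                       t_s = unname(t_of[as.character(frames)])),
         config = config),
    class = "rheo_frames"
  )
}

#' @export
print.rheo_frames <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<rheo_frames> %d frame(s) of %d x %d px\n",
              length(x$frames), d[1], d[2]))
  invisible(x)
}

#' Larva-free reference background
#'
#' The empty arena as the camera sees it: the pixel-wise mean over
#' `n_frames` noise-only frames (dark background plus the renderer's
#' additive intensity noise). This is what the mean image of a long,
#' many-cycle run converges to, and can be passed to
#' [measure_session_poses()] as an explicit background.
#'
#' @param config A [flow_config()].
#' @param noise A [render_noise()].
#' @param seed Integer seed (required when the noise amplitude is > 0).
#' @param n_frames Frames averaged.
#' @return A background matrix.
#' @export
render_empty_background <- function(config, noise = render_noise(),
                                    seed = NULL, n_frames = 20) {
  px <- config$pixel_size
  nr <- round(config$fov[4] / px)
  nc <- round(config$fov[3] / px)
  if (noise$intensity_sigma == 0) return(matrix(0, nr, nc))
  if (is.null(seed)) abort("`seed` is required when noise > 0.")
  acc <- matrix(0, nr, nc)
  for (f in seq_len(n_frames)) {
    m <- with_stream(seed, "empty-bg", f,
                     code = matrix(rnorm(nr * nc, 0, noise$intensity_sigma),
                                   nr, nc))
    m[m < 0] <- 0
    m[m > 1] <- 1
    acc <- acc + m
  }
  acc / n_frames
}

#' Write rendered frames to disk
#'
#' Writes a 16-bit grayscale multi-page TIFF (or a directory of numbered
#' PNGs) plus a sidecar CSV of timestamps (`frame`, `t_seconds`).
#'
#' @param x A `rheo_frames` object.
#' @param path Output file (TIFF) or directory (PNG).
#' @param format `"tiff"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("package `tiff` is required to write TIFF stacks.")
    }
    tiff::writeTIFF(x$frames, path, bits.per.sample = 16L)
    sidecar <- paste0(sub("\\.tiff?$", "", path), "_timestamps.csv")
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("package `png` is required to write PNG frames.")
    }
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(x$frames)) {
      png::writePNG(x$frames[[i]],
                    file.path(path, sprintf("frame_%06d.png", x$meta$frame[i])))
    }
    sidecar <- file.path(path, "timestamps.csv")
  }
  write.csv(data.frame(frame = x$meta$frame, t_seconds = x$meta$t_s),
            sidecar, row.names = FALSE)
  invisible(path)
}
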