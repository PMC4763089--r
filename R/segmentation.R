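#' Pixel-wise mean background image
#'
#' The run's average image: a pixel-wise mean over a sequence of frames.
#' Where larva occupancy is below ~50% of frames this converges to the empty
#' arena image (within noise).
#'
#' @param frames A `rheo_frames` object or a list of identically sized
#'   matrices (at least 2).
#' @return A matrix of the same size.
#' @export
build_background <- function(frames) {
  mats <- if (inherits(frames, "rheo_frames")) frames$frames else frames
  if (length(mats) < 2) abort("need at least 2 frames to build a background.")
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1)))) {
    abort("all frames must have identical dimensions.")
  }
  Reduce(`+`, mats) / length(mats)
}

# 1-D Gaussian kernel of a given box size (um) and sigma (um), converted to
# pixels; the box is rounded up to the nearest odd pixel count. The 2-D
# smoothing kernel is separable: outer(k1, k1).
gaussian_kernel1 <- function(blur_box, blur_sigma, pixel_size) {
  um <- pixel_size * 1000
  half <- ceiling((blur_box / um - 1) / 2)
  half <- max(half, 1L)
  ax <- (-half:half) * um
  k1 <- exp(-ax^2 / (2 * blur_sigma^2))
  k1 / sum(k1)
}

# separable Gaussian smoothing with replicate boundary (vectorized
# shift-and-add; the kernels here are ~5 taps, far cheaper than an FFT)
smooth_separable <- function(x, k1) {
  half <- (length(k1) - 1) / 2
  n <- nrow(x); m <- ncol(x)
  pr <- rbind(x[rep(1, half), , drop = FALSE], x,
              x[rep(n, half), , drop = FALSE])
  y <- matrix(0, n, m)
  for (j in seq_along(k1)) {
    y <- y + k1[j] * pr[j:(j + n - 1), , drop = FALSE]
  }
  pc <- cbind(y[, rep(1, half), drop = FALSE], y,
              y[, rep(m, half), drop = FALSE])
  z <- matrix(0, n, m)
  for (j in seq_along(k1)) {
    z <- z + k1[j] * pc[, j:(j + m - 1), drop = FALSE]
  }
  z
}

#' Segment larva blobs in one frame
#'
#' Subtracts the background, smooths with a Gaussian kernel (box and sigma
#' given in um, converted via the pixel size), thresholds (Otsu by default)
#' and extracts 4-connected components, discarding blobs smaller than
#' `min_area` pixels. Blobs touching the frame border are kept but flagged.
#'
#' @param frame A numeric matrix (one frame).
#' @param background The background matrix from [build_background()].
#' @param params A [segmentation_params()].
#' @param config A [flow_config()] (pixel size and field-of-view origin used
#'   to express centroids in arena mm).
#' @return A tibble, one row per blob, sorted by area (descending):
#'   `blob_id`, `area_px`, `cx_mm`, `cy_mm`, `on_border`, and a `pixels`
#'   list-column of per-pixel tibbles (`row`, `col`, `x_mm`, `y_mm`,
#'   `intensity` of the smoothed difference image). Zero rows when nothing is
#'   detected.
#' @export
segment_frame <- function(frame, background, params = segmentation_params(),
                          config) {
  if (!identical(dim(frame), dim(background))) {
    abort("`frame` and `background` must have the same shape.")
  }
  px <- config$pixel_size
  diffim <- frame - background
  k1 <- gaussian_kernel1(params$blur_box, params$blur_sigma, px)
  sm <- smooth_separable(diffim, k1)

  thr <- params$threshold
  if (identical(thr, "auto")) {
    rng <- range(sm)
    if (rng[2] <= rng[1]) return(empty_blob_table())
    otsu_thr <- otsu_threshold(pmin(pmax(sm, 0), 1))
    # noise floor: never threshold below 6 robust SDs of the difference
    # image (MAD on a pixel stride; the image is far larger than needed for
    # a stable scale estimate)
    thr <- max(otsu_thr, 6 * mad(sm[seq(1, length(sm), by = 7)]))
  }
  mask <- sm > thr
  if (!any(mask)) return(empty_blob_table())

  lab <- EBImage::bwlabel(mask)  # 4-connected
  idx <- which(lab > 0)
  by_blob <- split(idx, lab[idx])
  nr <- nrow(frame); nc <- ncol(frame)
  areas <- lengths(by_blob)
  keep <- which(areas >= params$min_area)
  if (length(keep) == 0) return(empty_blob_table())
  keep <- keep[order(areas[keep], decreasing = TRUE)]

  blobs <- lapply(keep, function(j) {
    ix <- by_blob[[j]]
    rows <- (ix - 1) %% nr + 1
    cols <- (ix - 1) %/% nr + 1
    x_mm <- (cols - 0.5) * px + config$fov[1]
    y_mm <- (rows - 0.5) * px + config$fov[2]
    list(
      area_px = length(ix),
      # centroid of the binarized body (the thin tail's intensity is
      # attenuated by the smoothing, so intensity weighting would bias the
      # position toward the head)
      cx_mm = mean(x_mm), cy_mm = mean(y_mm),
      on_border = any(rows == 1L | rows == nr | cols == 1L | cols == nc),
      pixels = tibble::new_tibble(
        list(row = rows, col = cols, x_mm = x_mm, y_mm = y_mm,
             intensity = sm[ix]),
        nrow = length(ix))
    )
  })
  tibble(
    blob_id = seq_along(blobs),
    area_px = unname(vapply(blobs, `[[`, integer(1), "area_px")),
    cx_mm = unname(vapply(blobs, `[[`, numeric(1), "cx_mm")),
    cy_mm = unname(vapply(blobs, `[[`, numeric(1), "cy_mm")),
    on_border = unname(vapply(blobs, `[[`, logical(1), "on_border")),
    pixels = unname(lapply(blobs, `[[`, "pixels"))
  )
}

# Otsu's threshold (maximal between-class variance) on a 256-bin histogram
# of values in [0, 1]; histogram-based, O(n) in the image size
otsu_threshold <- function(x, levels = 256L) {
  h <- as.numeric(tabulate(pmin(floor(x * levels), levels - 1L) + 1L,
                           nbins = levels))
  w <- cumsum(h)
  mu <- cumsum(h * (seq_len(levels) - 1))
  n <- w[levels]; mu_t <- mu[levels]
  valid <- w > 0 & w < n
  between <- rep(-Inf, levels)
  between[valid] <- (mu_t * w[valid] - n * mu[valid])^2 /
    (w[valid] * (n - w[valid]))
  (which.max(between) - 0.5) / levels
}

empty_blob_table <- function() {
  tibble(blob_id = integer(), area_px = integer(),
         cx_mm = numeric(), cy_mm = numeric(), on_border = logical(),
         pixels = list())
}
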