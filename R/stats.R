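# Population-level behavioral statistics.

#' Circular variance of a set of angles
#'
#' `1 - |mean resultant vector|`: 0 when all angles coincide, 1 when the
#' angles cancel exactly (e.g. equally spaced around the circle) or for a
#' large uniform sample. Invariant under a global rotation of all angles.
#'
#' @param angles Angles in radians (at least 1).
#' @return A value in [0, 1].
#' @examples
#' circular_variance(seq(0, 2 * pi, length.out = 9)[-9])  # exactly 1
#' circular_variance(rep(0.7, 100))                       # exactly 0
#' circular_variance(c(0, pi / 2))                        # 1 - sqrt(2)/2
#' @export
circular_variance <- function(angles) {
  if (length(angles) == 0) abort("`angles` must contain at least one angle.")
  v <- 1 - Mod(mean(exp(1i * angles)))
  min(max(v, 0), 1)
}

#' Label the counterflow swim sequence (CSS) onset of each track
#'
#' Automated criterion for "clear motion away from the suction source": the
#' CSS onset is the first bout starting a run of at least `run_length`
#' consecutive bouts that each (i) end well aligned with the outward radial
#' direction (`|alpha_offset| <= alpha_max`) and (ii) have an outward
#' impulse (`u cos(alpha_onset) > 0`).
#'
#' Detections that carry a quality flag (no tail beats found, unfit or
#' non-converged impulse fit) are not treated as bouts at all: they are
#' removed from the sequence before the run rule is applied, so a spurious
#' fragment between two genuine counterflow bouts does not break the run.
#'
#' @param bouts Bout table ([detect_track_bouts()] rows, any number of
#'   larvae; needs `larva_id`, `k`, `alpha_onset_rad`, `alpha_offset_rad`,
#'   `u_mm_s`; a `flag` column, when present, excludes flagged rows).
#' @param run_length Minimal run length (default 3).
#' @param alpha_max Maximal offset angle, rad (default 45 degrees).
#' @return A tibble `larva_id`, `onset_k` (NA when no qualifying run),
#'   `onset_t_s`, plus the criterion parameters as attributes.
#' @export
label_css <- function(bouts, run_length = 3, alpha_max = pi / 4) {
  bouts <- as_tibble(bouts)
  if ("flag" %in% names(bouts)) {
    bouts <- dplyr::filter(bouts, is.na(.data$flag) | .data$flag == "")
  }
  out <- bouts |>
    dplyr::arrange(.data$larva_id, .data$k) |>
    dplyr::group_by(.data$larva_id) |>
    dplyr::summarise(
      onset_k = {
        ok <- abs(.data$alpha_offset_rad) <= alpha_max &
          !is.na(.data$u_mm_s) & .data$u_mm_s * cos(.data$alpha_onset_rad) > 0
        find_run_start(ok, run_length, .data$k)
      },
      onset_t_s = if (is.na(onset_k)) NA_real_ else {
        .data$t_k_s[match(onset_k, .data$k)]
      },
      .groups = "drop"
    )
  attr(out, "params") <- list(run_length = run_length, alpha_max = alpha_max)
  out
}

# index (value of `k`) of the first element starting a run of >= len TRUEs
find_run_start <- function(ok, len, k) {
  ok[is.na(ok)] <- FALSE
  if (length(ok) < len) return(NA_integer_)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0) NA_integer_ else k[starts[hit[1]]]
}

#' Circular variance of the body angle aligned on the CSS onset
#'
#' Pools body angles across tracks into time bins relative to each track's
#' CSS onset and evaluates the circular variance per bin. By default the
#' pooled angles are the bout-onset angles; `mode = "frame"` pools the
#' per-frame angles of the pose table instead.
#'
#' @param bouts Bout table with `larva_id`, `t_k_s`, `alpha_onset_rad`.
#' @param labels Output of [label_css()]; tracks without an onset are
#'   dropped.
#' @param poses Pose table (`larva_id`, `t_s`, `alpha_rad`), required for
#'   `mode = "frame"`.
#' @param mode `"bout"` (default) or `"frame"`.
#' @param bin Bin width, s (default 0.5).
#' @param window Half-window around the onset, s (default 10).
#' @param n_min Minimal samples per bin; sparser bins are masked (NA).
#' @return A tibble `t_rel_s` (bin center), `var_c`, `n`.
#' @export
aligned_circvar <- function(bouts, labels, poses = NULL,
                            mode = c("bout", "frame"), bin = 0.5,
                            window = 10, n_min = 3) {
  mode <- match.arg(mode)
  labs <- dplyr::filter(as_tibble(labels), !is.na(.data$onset_t_s))
  if (nrow(labs) == 0) abort("no labeled tracks: no CSS onsets to align on.")
  bouts <- as_tibble(bouts)
  if ("flag" %in% names(bouts)) {
    # quality-flagged detections are not bouts (see label_css)
    bouts <- dplyr::filter(bouts, is.na(.data$flag) | .data$flag == "")
  }
  if (mode == "bout") {
    dat <- as_tibble(bouts) |>
      dplyr::inner_join(labs, by = "larva_id") |>
      dplyr::transmute(t_rel = .data$t_k_s - .data$onset_t_s,
                       angle = .data$alpha_onset_rad)
  } else {
    if (is.null(poses)) abort("`poses` is required for mode = \"frame\".")
    dat <- as_tibble(poses) |>
      dplyr::inner_join(labs, by = "larva_id") |>
      dplyr::transmute(t_rel = .data$t_s - .data$onset_t_s,
                       angle = .data$alpha_rad)
  }
  edges <- seq(-window, window, by = bin)
  dat |>
    dplyr::filter(.data$t_rel >= -window, .data$t_rel < window) |>
    dplyr::mutate(bin_i = findInterval(.data$t_rel, edges,
                                       rightmost.closed = TRUE)) |>
    dplyr::group_by(.data$bin_i) |>
    dplyr::summarise(var_c = circular_variance(.data$angle),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(tibble(bin_i = seq_len(length(edges) - 1)),
                      by = "bin_i") |>
    dplyr::arrange(.data$bin_i) |>
    dplyr::mutate(
      t_rel_s = edges[.data$bin_i] + bin / 2,
      n = dplyr::coalesce(.data$n, 0L),
      var_c = ifelse(.data$n >= n_min, .data$var_c, NA_real_)
    ) |>
    dplyr::select("t_rel_s", "var_c", "n")
}

#' Gaussian kernel density estimate
#'
#' Fixed-bandwidth Gaussian KDE on an automatically extended grid, normalized
#' so that the trapezoidal integral is 1 (within 1e-6).
#'
#' @param samples Numeric samples (at least 2).
#' @param bandwidth Gaussian kernel SD (> 0), in the units of `samples`.
#' @param n Grid size.
#' @return An object of class `rheo_kde`: a tibble `x`, `density`, with the
#'   bandwidth as an attribute.
#' @export
kde <- function(samples, bandwidth, n = 2048) {
  if (length(samples) < 2) abort("need at least 2 samples.")
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    abort("`bandwidth` must be > 0.")
  }
  d <- density(samples, bw = bandwidth, kernel = "gaussian", n = n, cut = 6)
  dens <- d$y / trapz(d$x, d$y)
  out <- tibble(x = d$x, density = dens)
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("rheo_kde", class(out))
  out
}

#' Two-sample distribution comparison
#'
#' Kolmogorov-Smirnov (maximal empirical-CDF gap, asymptotic p by default)
#' or Welch's unequal-variance t-test, with significance stars at
#' p < 1e-3 (`*`) and p < 1e-6 (`**`).
#'
#' @param x,y Numeric samples (at least 2 each).
#' @param method `"ks"` or `"welch"`.
#' @param exact For `"ks"`: passed to [stats::ks.test()] (default FALSE =
#'   asymptotic).
#' @return A one-row tibble `method`, `statistic`, `p_value`, `stars`.
#' @export
compare_distributions <- function(x, y, method = c("ks", "welch"),
                                  exact = FALSE) {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2) abort("both samples need >= 2 values.")
  if (method == "ks") {
    ht <- suppressWarnings(ks.test(x, y, exact = exact))
  } else {
    if (sd(x) == 0 && sd(y) == 0) {
      abort("degenerate zero-variance input for Welch's t-test.")
    }
    ht <- t.test(x, y, var.equal = FALSE)
  }
  p <- ht$p.value
  tibble(
    method = method, statistic = unname(ht$statistic), p_value = p,
    stars = if (p < 1e-6) "**" else if (p < 1e-3) "*" else ""
  )
}

#' Radial position-holding profile
#'
#' Bins the inter-bout distances `delta_k` by the radial position `rho_k` at
#' which each inter-bout starts, returning the mean and standard error per
#' bin (position holding shows as a profile near 0; attraction/repulsion
#' around an operating point shows as a zero crossing) plus the occupancy
#' histogram of rho.
#'
#' @param series Inter-bout series ([build_series()] rows, any number of
#'   larvae).
#' @param breaks Bin edges for `rho_k_mm` (mm).
#' @param n_min Bins with fewer pairs are masked.
#' @return A tibble `rho_mid_mm`, `delta_mean_mm`, `delta_se_mm`, `n`.
#' @export
radial_profile <- function(series, breaks = seq(0, 15, by = 1), n_min = 3) {
  series <- as_tibble(series)
  if (nrow(series) == 0) abort("empty series.")
  series |>
    dplyr::mutate(bin_i = findInterval(.data$rho_k_mm, breaks,
                                       rightmost.closed = TRUE)) |>
    dplyr::filter(.data$bin_i >= 1, .data$bin_i < length(breaks)) |>
    dplyr::group_by(.data$bin_i) |>
    dplyr::summarise(
      delta_mean = mean(.data$delta_mm),
      delta_se = if (dplyr::n() >= 2) sd(.data$delta_mm) / sqrt(dplyr::n())
                 else NA_real_,
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::right_join(tibble(bin_i = seq_len(length(breaks) - 1)),
                      by = "bin_i") |>
    dplyr::arrange(.data$bin_i) |>
    dplyr::transmute(
      rho_mid_mm = (breaks[.data$bin_i] + breaks[.data$bin_i + 1]) / 2,
      n = dplyr::coalesce(.data$n, 0L),
      delta_mean_mm = ifelse(.data$n >= n_min, .data$delta_mean, NA_real_),
      delta_se_mm = ifelse(.data$n >= n_min, .data$delta_se, NA_real_)
    ) |>
    dplyr::relocate("rho_mid_mm", "delta_mean_mm", "delta_se_mm", "n")
}

#' CSS onset summary: radial position and fluid speed at the first CSS bout
#'
#' Group means (with standard errors) of the radial position `rho_1` and
#' fluid speed `v_1` at the onset bout of each track's CSS, grouped e.g. by
#' flow rate or age, plus a KS test of the pooled `rho_1` against radii of
#' positions drawn uniformly in the field of view (seeded).
#'
#' @param bouts Bout table (needs `larva_id`, `k`, `rho_k_mm`, `v_f_mm_s`).
#' @param labels Output of [label_css()].
#' @param group Optional vector (or column name in `bouts`) grouping the
#'   tracks; a per-track value, joined by `larva_id`, as a two-column data
#'   frame `larva_id`, `group`. NULL = one group.
#' @param config A [flow_config()] (field of view for the uniform null).
#' @param n_null Size of the uniform null sample.
#' @param seed Seed for the null draw.
#' @return A list of class `rheo_onset_summary`: `groups` (tibble `group`,
#'   `n`, `rho1_mean_mm`, `rho1_se_mm`, `v1_mean_mm_s`, `v1_se_mm_s`) and
#'   `ks_uniform` (tibble from [compare_distributions()]).
#' @export
onset_summary <- function(bouts, labels, group = NULL, config,
                          n_null = 2000, seed = 1) {
  bouts <- as_tibble(bouts)
  labs <- dplyr::filter(as_tibble(labels), !is.na(.data$onset_k))
  onset <- bouts |>
    dplyr::inner_join(labs, by = "larva_id") |>
    dplyr::filter(.data$k == .data$onset_k)
  if (nrow(onset) == 0) abort("no CSS onsets to summarize.")
  onset$group <- if (is.null(group)) {
    "all"
  } else {
    g <- as_tibble(group)
    g[["group"]][match(onset$larva_id, g[["larva_id"]])]
  }
  groups <- onset |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      rho1_mean_mm = mean(.data$rho_k_mm),
      rho1_se_mm = if (dplyr::n() >= 2) sd(.data$rho_k_mm) / sqrt(dplyr::n())
                   else NA_real_,
      v1_mean_mm_s = mean(.data$v_f_mm_s, na.rm = TRUE),
      v1_se_mm_s = if (sum(!is.na(.data$v_f_mm_s)) >= 2) {
        sd(.data$v_f_mm_s, na.rm = TRUE) / sqrt(sum(!is.na(.data$v_f_mm_s)))
      } else NA_real_,
      .groups = "drop"
    )
  null_rho <- with_stream(seed, "onset-null", code = {
    fov <- config$fov
    px <- cbind(runif(n_null, fov[1], fov[1] + fov[3]),
                runif(n_null, fov[2], fov[2] + fov[4]))
    sqrt((px[, 1] - config$sink[1])^2 + (px[, 2] - config$sink[2])^2)
  })
  ks <- if (nrow(onset) >= 2) {
    compare_distributions(onset$rho_k_mm, null_rho, method = "ks")
  } else {
    # a single onset cannot support a two-sample test
    tibble(method = "ks", statistic = NA_real_, p_value = NA_real_,
           stars = "")
  }
  structure(list(groups = groups, ks_uniform = ks, n_onsets = nrow(onset)),
            class = "rheo_onset_summary")
}

#' @export
print.rheo_onset_summary <- function(x, ...) {
  cat("<rheo_onset_summary>", x$n_onsets, "CSS onsets\n")
  print(x$groups)
  cat(sprintf("KS vs uniform FOV positions: D = %.3f, p = %.3g\n",
              x$ks_uniform$statistic, x$ks_uniform$p_value))
  invisible(x)
}

#' @export
tidy.rheo_onset_summary <- function(x, ...) x$groups

#' @export
glance.rheo_onset_summary <- function(x, ...) {
  tibble(n_onsets = x$n_onsets, ks_D = x$ks_uniform$statistic,
         ks_p = x$ks_uniform$p_value)
}

#' Egocentric density of the suction point
#'
#' Maps the suction point into each larva's reference frame (origin at the
#' larva, forward axis along the heading, lateral axis to the right) and
#' returns the normalized 2D histogram: where, relative to its own body, the
#' larva keeps the flow source.
#'
#' @param poses Pose table (`x_mm`, `y_mm`, `heading_rad`; a `phase` column,
#'   if present, can be used to facet upstream).
#' @param config A [flow_config()].
#' @param extent Half-extent of the egocentric grid, mm.
#' @param bin Bin size, mm.
#' @return A tibble `forward_mm`, `lateral_mm`, `density` (integrates to 1
#'   over the grid), of class `rheo_egodensity`.
#' @export
egocentric_density <- function(poses, config, extent = 15, bin = 0.5) {
  poses <- as_tibble(poses)
  dx <- config$sink[1] - poses$x_mm
  dy <- config$sink[2] - poses$y_mm
  phi <- poses$heading_rad
  forward <- dx * cos(phi) + dy * sin(phi)
  lateral <- dx * sin(phi) - dy * cos(phi)   # right of the heading
  edges <- seq(-extent, extent, by = bin)
  fi <- findInterval(forward, edges, rightmost.closed = TRUE)
  li <- findInterval(lateral, edges, rightmost.closed = TRUE)
  keep <- fi >= 1 & fi < length(edges) & li >= 1 & li < length(edges)
  counts <- table(factor(fi[keep], levels = seq_len(length(edges) - 1)),
                  factor(li[keep], levels = seq_len(length(edges) - 1)))
  dens <- as.numeric(counts) / (sum(counts) * bin^2)
  mids <- edges[-length(edges)] + bin / 2
  out <- tibble(
    forward_mm = rep(mids, times = length(mids)),
    lateral_mm = rep(mids, each = length(mids)),
    density = dens
  )
  class(out) <- c("rheo_egodensity", class(out))
  out
}
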