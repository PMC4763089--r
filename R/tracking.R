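# Frame-to-frame identity linking in the spirit of nearest-neighbour
# particle tracking: per frame pair, the assignment minimizing the total
# squared displacement among assignments whose individual displacements are
# all <= max_disp, with unmatched detections starting new tracks and tracks
# allowed to stay dormant for up to `memory` frames before re-attaching.

# Exact minimum-cost assignment of detections to candidate tracks by
# depth-first branch and bound. `cand` is a list (one element per detection)
# of data frames with columns `track` (0 = start a new track) and `cost`.
# Detections are explored in order; candidates must be pre-sorted by track id
# with the new-track option last, so that among equal-cost optima the
# lexicographically first (smallest track ids) is kept.
solve_assignment <- function(cand) {
  n <- length(cand)
  best <- list(cost = Inf, assign = integer(n))
  cur <- integer(n)
  # lower bound: each remaining detection costs at least its cheapest option
  min_costs <- vapply(cand, function(d) min(d$cost), numeric(1))
  suffix_lb <- rev(cumsum(rev(min_costs)))
  recurse <- function(i, used, acc) {
    if (acc + (if (i <= n) suffix_lb[i] else 0) >= best$cost) return()
    if (i > n) {
      best <<- list(cost = acc, assign = cur)
      return()
    }
    d <- cand[[i]]
    for (j in seq_len(nrow(d))) {
      tr <- d$track[j]
      if (tr != 0 && tr %in% used) next
      cur[i] <<- tr
      recurse(i + 1, if (tr != 0) c(used, tr) else used, acc + d$cost[j])
    }
  }
  recurse(1, integer(0), 0)
  best$assign
}

#' Link per-frame poses into identity-preserving tracks
#'
#' Assigns detections of consecutive frames by exact minimization of the
#' total squared displacement, subject to every displacement being at most
#' `max_disp`; unmatched detections start new tracks, and a detection may
#' re-attach to a track that has been dormant for at most `memory` frames.
#' Leaving a detection unmatched carries a cost of `max_disp^2`. Detections
#' within a frame are processed in a canonical (x, y) order, so the result
#' does not depend on the input row order. Gap frames are left absent (no
#' interpolation).
#'
#' @param poses A tibble of per-frame poses with at least `frame`, `x_mm`,
#'   `y_mm` (e.g. rows of [extract_poses()] stacked over frames).
#' @param max_disp Maximal displacement between consecutive detections, mm.
#' @param memory Maximal dormancy, frames.
#' @return The input tibble with columns `larva_id` (track id, in order of
#'   track creation) and `gap_frames` (frames skipped since the previous
#'   sample of the same track), sorted by (larva_id, frame).
#' @export
link_tracks <- function(poses, max_disp = 3.5, memory = 100) {
  poses <- as_tibble(poses)
  stopifnot(all(c("frame", "x_mm", "y_mm") %in% names(poses)))
  poses <- dplyr::arrange(poses, .data$frame, .data$x_mm, .data$y_mm)
  frames <- unique(poses$frame)
  idx_by_frame <- split(seq_len(nrow(poses)), poses$frame)

  track_last <- list()   # per track: list(pos, frame)
  n_tracks <- 0L
  larva_id <- integer(nrow(poses))
  gap_frames <- integer(nrow(poses))

  for (f in frames) {
    rows <- idx_by_frame[[as.character(f)]]
    det <- cbind(poses$x_mm[rows], poses$y_mm[rows])
    active <- which(vapply(track_last, function(tr) {
      f - tr$frame - 1 <= memory && tr$frame < f
    }, logical(1)))
    cand <- lapply(seq_len(nrow(det)), function(i) {
      if (length(active)) {
        dd2 <- vapply(active, function(k) {
          sum((det[i, ] - track_last[[k]]$pos)^2)
        }, numeric(1))
        ok <- dd2 <= max_disp^2
        d <- data.frame(track = active[ok], cost = dd2[ok])
        d <- d[order(d$track), , drop = FALSE]
      } else {
        d <- data.frame(track = integer(), cost = numeric())
      }
      rbind(d, data.frame(track = 0L, cost = max_disp^2))
    })
    assign <- solve_assignment(cand)
    for (i in seq_along(rows)) {
      tr <- assign[i]
      if (tr == 0L) {
        n_tracks <- n_tracks + 1L
        tr <- n_tracks
        track_last[[tr]] <- list(pos = det[i, ], frame = f)
        gap_frames[rows[i]] <- 0L
      } else {
        gap_frames[rows[i]] <- f - track_last[[tr]]$frame - 1L
        track_last[[tr]] <- list(pos = det[i, ], frame = f)
      }
      larva_id[rows[i]] <- tr
    }
  }
  poses$larva_id <- larva_id
  poses$gap_frames <- gap_frames
  dplyr::arrange(poses, .data$larva_id, .data$frame)
}

#' Filter and truncate linked tracks
#'
#' Automatic replacement for manual trajectory curation: drops tracks shorter
#' than `min_duration` and truncates every track at the first frame where
#' another track's detection comes closer than `contact_exclusion` (merged or
#' touching larvae cannot be attributed reliably).
#'
#' @param tracks Output of [link_tracks()] (needs `larva_id`, `frame`,
#'   `x_mm`, `y_mm` and a time column `t_s` if `min_duration` > 0).
#' @param min_duration Minimal track duration, s.
#' @param contact_exclusion Contact distance, mm (0 disables).
#' @return The filtered track tibble.
#' @export
filter_tracks <- function(tracks, min_duration = 0, contact_exclusion = 0) {
  tracks <- as_tibble(tracks)
  if (contact_exclusion > 0 && dplyr::n_distinct(tracks$larva_id) > 1) {
    contacts <- tracks |>
      dplyr::inner_join(tracks, by = "frame", suffix = c("", ".o"),
                        relationship = "many-to-many") |>
      dplyr::filter(.data$larva_id != .data$larva_id.o) |>
      dplyr::mutate(dist = sqrt((.data$x_mm - .data$x_mm.o)^2 +
                                (.data$y_mm - .data$y_mm.o)^2)) |>
      dplyr::filter(.data$dist < contact_exclusion)
    if (nrow(contacts) > 0) {
      cut_at <- contacts |>
        dplyr::group_by(.data$larva_id) |>
        dplyr::summarise(first_contact = min(.data$frame), .groups = "drop")
      tracks <- tracks |>
        dplyr::left_join(cut_at, by = "larva_id") |>
        dplyr::filter(is.na(.data$first_contact) |
                        .data$frame < .data$first_contact) |>
        dplyr::select(-"first_contact")
    }
  }
  if (min_duration > 0) {
    tracks <- tracks |>
      dplyr::group_by(.data$larva_id) |>
      dplyr::filter(max(.data$t_s) - min(.data$t_s) >= min_duration) |>
      dplyr::ungroup()
  }
  tracks
}
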