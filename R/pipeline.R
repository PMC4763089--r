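# End-to-end orchestration: simulate -> render -> segment -> posture ->
# track -> bouts -> stats, with one flat configuration, seeded
# reproducibility and a manifest accompanying every table.

#' Pipeline configuration
#'
#' One flat configuration object holding all stage parameters. Every
#' stochastic stage derives its randomness from `seed`.
#'
#' @param flow A [flow_config()].
#' @param larva A [larva_model()].
#' @param behavior A [behavior_params()].
#' @param noise A [render_noise()].
#' @param seg A [segmentation_params()].
#' @param n_larvae,duration Session size.
#' @param seed Integer seed.
#' @param detector List: `threshold`, `min_duration`, `beat_threshold`.
#' @param tracking List: `max_disp`, `memory`, `min_duration`,
#'   `contact_exclusion`.
#' @param css List: `run_length`, `alpha_max`.
#' @param chunk Frames per processing chunk (memory control).
#' @param bg_stride Background is the pixel-wise mean over every
#'   `bg_stride`-th frame.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(flow = flow_config(), larva = larva_model(),
                            behavior = behavior_params(),
                            noise = render_noise(),
                            seg = segmentation_params(),
                            n_larvae = 2, duration = 10, seed = 1,
                            detector = list(threshold = 5,
                                            min_duration = 0.04,
                                            beat_threshold = 0.1),
                            tracking = list(max_disp = 3.5, memory = 100,
                                            min_duration = 0,
                                            contact_exclusion = 0),
                            css = list(run_length = 3, alpha_max = pi / 4),
                            chunk = 100, bg_stride = 10) {
  structure(
    list(flow = flow, larva = larva, behavior = behavior, noise = noise,
         seg = seg, n_larvae = n_larvae, duration = duration, seed = seed,
         detector = detector, tracking = tracking, css = css,
         chunk = chunk, bg_stride = bg_stride),
    class = "pipeline_config"
  )
}

#' Measure poses of a synthetic session through the imaging pipeline
#'
#' Renders the session's frames (in chunks, so the full stack is never held
#' in memory), builds the background as the pixel-wise mean over a stride
#' subsample of rendered frames, segments every frame and extracts poses,
#' using the previous frame's poses to stabilize head identification.
#'
#' @param session A [simulate_session()] result.
#' @param config A [pipeline_config()] (noise, segmentation, chunking).
#' @param background Optional explicit background matrix (e.g. a larva-free
#'   reference image of the arena). Default NULL: the pixel-wise mean over a
#'   stride subsample of the session's own frames. Note the mean image of a
#'   short single-cycle session contains a ghost wherever a larva holds
#'   position; a multi-cycle assay's run average (or a larva-free reference)
#'   does not.
#' @return A pose tibble with `frame` and `t_s` (one row per detected blob).
#' @export
measure_session_poses <- function(session, config = pipeline_config(),
                                  background = NULL) {
  flow <- session$config
  frames_all <- seq_len(session$n_frames)
  t_all <- sort(unique(session$poses$t_s))

  if (is.null(background)) {
    bg_frames <- frames_all[seq(1, length(frames_all),
                                by = config$bg_stride)]
    bg_sum <- NULL
    for (ch in split(bg_frames,
                     ceiling(seq_along(bg_frames) / config$chunk))) {
      fr <- render_frames(session, noise = config$noise, seed = config$seed,
                          frames = ch, out_of_view = "skip")
      s <- Reduce(`+`, fr$frames)
      bg_sum <- if (is.null(bg_sum)) s else bg_sum + s
    }
    background <- bg_sum / length(bg_frames)
  }

  prev <- NULL
  out <- vector("list", length(frames_all))
  for (ch in split(frames_all, ceiling(frames_all / config$chunk))) {
    fr <- render_frames(session, noise = config$noise, seed = config$seed,
                        frames = ch, out_of_view = "skip")
    for (i in seq_along(ch)) {
      f <- ch[i]
      blobs <- segment_frame(fr$frames[[i]], background, config$seg, flow)
      poses <- extract_poses(blobs, flow, previous_poses = prev,
                             t = t_all[f],
                             match_dist = config$tracking$max_disp)
      if (nrow(poses) > 0) {
        poses$frame <- f
        prev <- poses
        out[[f]] <- poses
      }
    }
  }
  dplyr::bind_rows(out) |> dplyr::relocate("frame")
}

#' Run the full pipeline on a synthetic session
#'
#' Executes the requested stages in order and, when `out_dir` is given,
#' writes each stage's table as CSV plus a `manifest.json` recording the
#' stage list, a configuration hash and the seed (rerunning with the same
#' configuration and seed is bit-identical).
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("simulate", "measure", "track", "bouts",
#'   "stats")`, in pipeline order; later stages require the earlier ones.
#' @param out_dir Optional output directory.
#' @return A list of class `rheo_run` with the stage outputs that were
#'   computed: `session`, `poses`, `tracks`, `bouts`, `series`, `labels`,
#'   `stats`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "measure", "track", "bouts",
                                    "stats"),
                         out_dir = NULL) {
  all_stages <- c("simulate", "measure", "track", "bouts", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(s) s %in% stages
  if (!identical(stages, all_stages[seq_along(stages)])) {
    miss <- setdiff(all_stages[seq_len(max(match(stages, all_stages)))],
                    stages)
    if (length(miss)) {
      abort(paste0("missing upstream stage(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  res <- list()

  if (need("simulate")) {
    res$session <- simulate_session(config$flow, config$larva,
                                    config$behavior,
                                    n_larvae = config$n_larvae,
                                    duration = config$duration,
                                    seed = config$seed)
  }
  if (need("measure")) {
    res$poses <- measure_session_poses(res$session, config)
  }
  if (need("track")) {
    res$tracks <- link_tracks(res$poses,
                              max_disp = config$tracking$max_disp,
                              memory = config$tracking$memory) |>
      filter_tracks(min_duration = config$tracking$min_duration,
                    contact_exclusion = config$tracking$contact_exclusion)
  }
  if (need("bouts")) {
    fr <- config$flow$frame_rate
    res$bouts <- res$tracks |>
      dplyr::group_split(.data$larva_id) |>
      purrr::map_dfr(detect_track_bouts, frame_rate = fr,
                     threshold = config$detector$threshold,
                     min_duration = config$detector$min_duration,
                     beat_threshold = config$detector$beat_threshold)
    res$series <- res$bouts |>
      dplyr::group_split(.data$larva_id) |>
      purrr::map_dfr(build_series)
  }
  if (need("stats")) {
    res$labels <- label_css(res$bouts, run_length = config$css$run_length,
                            alpha_max = config$css$alpha_max)
    stats_list <- list()
    if (any(!is.na(res$labels$onset_k))) {
      stats_list$aligned_circvar <-
        aligned_circvar(res$bouts, res$labels)
      stats_list$onset <- onset_summary(res$bouts, res$labels,
                                        config = config$flow,
                                        seed = config$seed)
    }
    if (nrow(res$series) > 0) {
      stats_list$radial_profile <- radial_profile(res$series)
    }
    res$stats <- stats_list
  }

  if (!is.null(out_dir)) write_run(res, config, stages, out_dir)
  structure(res, class = "rheo_run")
}

write_run <- function(res, config, stages, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  tables <- list(
    truth_poses = res$session$poses, truth_bouts = res$session$bouts,
    poses = res$poses, tracks = res$tracks, bouts = res$bouts,
    series = res$series, labels = res$labels
  )
  written <- character()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.null(tb)) next
    tb <- dplyr::select(as_tibble(tb), -dplyr::any_of("pixels"))
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tb, path, row.names = FALSE)
    written <- c(written, basename(path))
  }
  if (!is.null(res$stats)) {
    for (nm in names(res$stats)) {
      obj <- res$stats[[nm]]
      tb <- if (inherits(obj, "rheo_onset_summary")) obj$groups else obj
      path <- file.path(out_dir, paste0("stats_", nm, ".csv"))
      write.csv(as_tibble(tb), path, row.names = FALSE)
      written <- c(written, basename(path))
    }
  }
  jsonlite::write_json(
    list(stages = stages, config_hash = cfg_hash, seed = config$seed,
         files = written),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.rheo_run <- function(x, ...) {
  cat("<rheo_run> stages:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
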