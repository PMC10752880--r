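# End-to-end analysis of one video and batch orchestration over many.

#' Analyse one image stack end-to-end
#'
#' Runs the full chain on an in-memory stack: optional shift correction,
#' per-frame segmentation, track building with gap repair, optional track
#' smoothing, validity filtering, and all migration metrics.
#'
#' @param stack A `pt_stack` from [read_stack()] or [generate_video()].
#' @param settings A [settings()] object.
#' @param keep_labels Keep per-frame label matrices for overlay rendering.
#' @return A `pt_run` object: list with `settings`, `shifts` (tibble or
#'   NULL), `segmentations`, `tracks` (all), `valid_tracks`, `metrics`
#'   (per valid track), `frame_summary` (per time step), `velocity_dist`,
#'   `counts`, `dt`. Use [tidy()] for per-track metrics and [glance()] for
#'   the one-row video summary.
#' @export
track_video <- function(stack, settings = default_settings(), keep_labels = FALSE) {
  shifts <- NULL
  if (settings$shift_correction) {
    al <- align_stack(stack, settings)
    stack <- al$stack
    shifts <- al$shifts
  }
  if (settings$flat_field_correction) {
    # with the whole series at hand the static background comes from the
    # temporal median, not the per-frame spatial estimate
    stack <- flat_field_stack(stack, settings)
    settings <- settings(flat_field_correction = FALSE, .base = settings)
  }
  segs <- lapply(stack$frames, segment_frame, settings = settings,
                 keep_labels = keep_labels)
  tracks <- build_tracks(segs, settings, dt = stack$dt)
  if (settings$smoothing_iterations > 0)
    tracks <- smooth_tracks(tracks, settings$smoothing_iterations)
  valid <- filter_valid_tracks(tracks, settings$shortest_cell_track)
  metrics <- if (nrow(valid)) track_metrics(valid) else NULL
  if (!is.null(metrics) && settings$wound_healing_mode)
    metrics <- wound_signed_fmi(metrics)
  frame_summary <- if (nrow(valid)) mean_velocity_over_time(valid) else NULL
  vdist <- if (nrow(valid)) {
    v <- step_velocities(valid)
    if (length(v) >= 10L) tryCatch(velocity_distribution(v), warning = function(w) NULL)
    else NULL
  } else NULL
  structure(list(
    settings = settings, shifts = shifts, segmentations = segs,
    tracks = tracks, valid_tracks = valid, metrics = metrics,
    frame_summary = frame_summary, velocity_dist = vdist,
    counts = count_cells_over_time(segs), dt = stack$dt
  ), class = "pt_run")
}

#' @export
print.pt_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<phasetrack run: %d frames, %d tracks (%d valid), mean velocity %.3g um/min>\n",
              g$n_frames, g$n_tracks, g$n_valid_tracks, g$mean_velocity))
  invisible(x)
}

#' @rdname track_video
#' @param x A `pt_run`.
#' @param ... Unused.
#' @method tidy pt_run
#' @export
tidy.pt_run <- function(x, ...) {
  x$metrics %||% tibble()
}

#' @rdname track_video
#' @method glance pt_run
#' @export
glance.pt_run <- function(x, ...) {
  fs <- x$frame_summary
  m <- x$metrics
  tibble(
    n_frames = nrow(x$counts),
    n_cells_first = x$counts$n_identified[1],
    n_cells_last = x$counts$n_identified[nrow(x$counts)],
    n_tracks = dplyr::n_distinct(x$tracks$track),
    n_valid_tracks = if (nrow(x$valid_tracks)) dplyr::n_distinct(x$valid_tracks$track) else 0L,
    # the population velocity: per-step means averaged over all time steps
    mean_velocity = if (!is.null(fs)) mean(fs$mean_velocity, na.rm = TRUE) else NA_real_,
    mode_velocity = if (!is.null(x$velocity_dist)) x$velocity_dist$mode else NA_real_,
    median_velocity = if (!is.null(x$velocity_dist)) x$velocity_dist$median else NA_real_,
    mean_directness = if (!is.null(m)) mean(m$directness, na.rm = TRUE) else NA_real_,
    mean_fmi_x = if (!is.null(m)) mean(m$fmi_x, na.rm = TRUE) else NA_real_,
    mean_fmi_y = if (!is.null(m)) mean(m$fmi_y, na.rm = TRUE) else NA_real_,
    mean_accumulated_distance = if (!is.null(m)) mean(m$accumulated_distance) else NA_real_,
    mean_euclidean_distance = if (!is.null(m)) mean(m$euclidean_distance) else NA_real_,
    max_velocity_sum_per_cell = if (!is.null(fs)) max(fs$velocity_sum_per_cell, na.rm = TRUE) else NA_real_
  )
}

#' @method tidy pt_distribution
#' @export
tidy.pt_distribution <- function(x, ...) x$bins

#' @method glance pt_distribution
#' @export
glance.pt_distribution <- function(x, ...) {
  tibble(mode = x$mode, median = x$median, mean = x$mean,
         n = x$n, bin_width = x$bin_width)
}

#' @method tidy pt_agreement
#' @export
tidy.pt_agreement <- function(x, ...) x$differences

#' @method glance pt_agreement
#' @export
glance.pt_agreement <- function(x, ...) {
  tibble(bias = x$bias, lower = x$lower, upper = x$upper,
         n_pairs = nrow(x$differences))
}

# ---- tables --------------------------------------------------------------

#' Write the CSV result tables of a run
#'
#' Four tables with deterministic column order and a locale-independent
#' decimal point: `Track_summary.csv` (one row per valid track),
#' `Track_steps.csv` (track, frame, position, step velocity, repaired
#' flag), `Frame_summary.csv` (per time step: cell count, mean velocity,
#' velocity sum per cell), and the one-row `Overall_summary.csv`. When
#' shift correction ran, `Shifts.csv` records the per-frame corrections.
#'
#' @param run A `pt_run`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (e.g. the video stem).
#' @return Tibble of the files written, invisibly.
#' @export
write_tables <- function(run, dir, prefix = "phasetrack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  files <- character(0)

  trk <- run$metrics %||%
    tibble(track = integer(), n_steps = integer(), duration = numeric(),
           mean_step_velocity = numeric(), accumulated_distance = numeric(),
           euclidean_distance = numeric(), euclidean_velocity = numeric(),
           directness = numeric(), fmi_x = numeric(), fmi_y = numeric(),
           start_x = numeric(), start_y = numeric())
  write.csv(trk, p("Track_summary.csv"), row.names = FALSE)
  files <- c(files, p("Track_summary.csv"))

  dtv <- run$dt
  steps <- run$valid_tracks |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::group_by(.data$track) |>
    dplyr::mutate(step_velocity = hypot(.data$x - dplyr::lag(.data$x),
                                        .data$y - dplyr::lag(.data$y)) / dtv) |>
    dplyr::ungroup() |>
    dplyr::select("track", "frame", "x", "y", "step_velocity", "repaired")
  write.csv(steps, p("Track_steps.csv"), row.names = FALSE)
  files <- c(files, p("Track_steps.csv"))

  fr <- run$counts
  if (!is.null(run$frame_summary)) {
    fr <- dplyr::left_join(fr, run$frame_summary,
                           by = c(frame = "step"))
  }
  write.csv(fr, p("Frame_summary.csv"), row.names = FALSE)
  files <- c(files, p("Frame_summary.csv"))

  write.csv(glance(run), p("Overall_summary.csv"), row.names = FALSE)
  files <- c(files, p("Overall_summary.csv"))

  if (!is.null(run$shifts)) {
    write.csv(run$shifts, p("Shifts.csv"), row.names = FALSE)
    files <- c(files, p("Shifts.csv"))
  }
  invisible(tibble(file = files))
}

# ---- overlay video -------------------------------------------------------

.track_palette <- function(n) {
  grDevices::hsv(h = (seq_len(n) * 0.6180339887) %% 1, s = 0.9, v = 0.9)
}

#' Write an annotated overlay video (multi-page RGB TIFF)
#'
#' Identified cells are drawn as green outlines; each valid track present
#' in the frame is a coloured dot with its polyline trail up to the
#' current frame. Tracks whose cell has left the series are not drawn (use
#' the trajectory plots to see all valid tracks). With no annotations the
#' written frames are identical to the input.
#'
#' @param stack A `pt_stack` (aligned if alignment was used).
#' @param path Output `.tif` path.
#' @param segmentations Optional list of `pt_segmentation` with label
#'   matrices (from [segment_frame()] with `keep_labels = TRUE`).
#' @param tracks Optional valid-track tibble.
#' @return `path`, invisibly.
#' @export
write_overlay_video <- function(stack, path, segmentations = NULL, tracks = NULL) {
  H <- nrow(stack$frames[[1]]); W <- ncol(stack$frames[[1]])
  px <- stack$pixel_size
  ids <- if (!is.null(tracks) && nrow(tracks)) sort(unique(tracks$track)) else integer(0)
  cols <- .track_palette(length(ids))
  col_rgb <- grDevices::col2rgb(cols) / 255
  pages <- vector("list", length(stack$frames))
  for (t in seq_along(stack$frames)) {
    g <- clamp(round(stack$frames[[t]]), 0, 255) / 255
    rgb <- array(g, dim = c(H, W, 3))
    if (!is.null(segmentations)) {
      lbl <- attr(segmentations[[t]], "labels")
      if (!is.null(lbl)) {
        off <- attr(segmentations[[t]], "offset_px") %||% c(x = 0, y = 0)
        fg <- lbl > 0L
        hh <- nrow(lbl); ww <- ncol(lbl)
        pad <- matrix(FALSE, hh + 2L, ww + 2L); pad[2:(hh + 1), 2:(ww + 1)] <- fg
        edge <- fg & !(pad[1:hh, 2:(ww + 1)] & pad[3:(hh + 2), 2:(ww + 1)] &
                       pad[2:(hh + 1), 1:ww] & pad[2:(hh + 1), 3:(ww + 2)])
        er <- which(edge, arr.ind = TRUE)
        rr <- er[, 1] + off[["y"]]; cc <- er[, 2] + off[["x"]]
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        idx <- cbind(rr[ok], cc[ok])
        rgb[cbind(idx, 1)] <- 0; rgb[cbind(idx, 2)] <- 0.9; rgb[cbind(idx, 3)] <- 0
      }
    }
    if (length(ids)) {
      present <- tracks |>
        dplyr::filter(.data$frame <= t) |>
        dplyr::group_by(.data$track) |>
        dplyr::filter(any(.data$frame == t)) |>
        dplyr::arrange(.data$frame) |>
        dplyr::ungroup()
      for (k in seq_along(ids)) {
        tr <- present[present$track == ids[k], ]
        if (!nrow(tr)) next
        rcol <- col_rgb[1, k]; gcol <- col_rgb[2, k]; bcol <- col_rgb[3, k]
        rpts <- round(tr$y / px) + 1L; cpts <- round(tr$x / px) + 1L
        if (nrow(tr) > 1L) {
          for (s in seq_len(nrow(tr) - 1L)) {
            ln <- bresenham(rpts[s], cpts[s], rpts[s + 1L], cpts[s + 1L])
            ok <- ln[, 1] >= 1 & ln[, 1] <= H & ln[, 2] >= 1 & ln[, 2] <= W
            ln <- ln[ok, , drop = FALSE]
            rgb[cbind(ln, 1)] <- rcol; rgb[cbind(ln, 2)] <- gcol; rgb[cbind(ln, 3)] <- bcol
          }
        }
        r0 <- tail(rpts, 1); c0 <- tail(cpts, 1)
        dot <- expand.grid(r = clamp(r0 + (-1:1), 1, H), c = clamp(c0 + (-1:1), 1, W))
        rgb[cbind(dot$r, dot$c, 1)] <- rcol
        rgb[cbind(dot$r, dot$c, 2)] <- gcol
        rgb[cbind(dot$r, dot$c, 3)] <- bcol
      }
    }
    pages[[t]] <- rgb
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

# ---- batch ---------------------------------------------------------------

#' Batch-process several videos with identical settings
#'
#' Each readable video is analysed independently; results (CSV tables, the
#' settings actually used, optionally plots and the overlay video) go into
#' a sibling folder named `<video-stem>_results`. Per-video failures are
#' logged and skipped; processing continues. A cross-video summary with one
#' row per successfully processed video is returned and written next to
#' the first video.
#'
#' @param video_paths Character vector of TIFF image-series paths.
#' @param settings A [settings()] object applied to every video.
#' @param output_dir Where to place result folders and the summary
#'   (default: alongside each video).
#' @param overlay Also write the annotated overlay TIFF per video.
#' @param plots Also write PNG plots per video.
#' @return A list with `summary` (tibble, one row per processed video),
#'   `runs` (named list of `pt_run`), `failures` (tibble `video`,
#'   `error`), `log` (path to the batch log).
#' @export
run_batch <- function(video_paths, settings = default_settings(),
                      output_dir = NULL, overlay = FALSE, plots = FALSE) {
  if (length(video_paths) == 0L || !any(file.exists(video_paths) | dir.exists(video_paths)))
    stopf("No readable videos given to run_batch()")
  base_dir <- output_dir %||% dirname(video_paths[1])
  dir.create(base_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(base_dir, "phasetrack_batch.log")
  logline <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                       sprintf(...)), file = log_path, append = TRUE)
  logline("Batch start: %d video(s)", length(video_paths))
  for (field in names(unclass(settings)))
    logline("setting %s = %s", field, format(settings[[field]]))

  runs <- list(); rows <- list(); fails <- list()
  for (v in video_paths) {
    stem <- sub("\\.[^.]*$", "", basename(v))
    res <- tryCatch({
      stack <- read_stack(v, settings)
      run <- track_video(stack, settings, keep_labels = overlay)
      out_dir <- file.path(output_dir %||% dirname(v), paste0(stem, "_results"))
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      save_settings(settings, file.path(out_dir, paste0(stem, "_settings_used.txt")))
      write_tables(run, out_dir, prefix = stem)
      if (nrow(run$valid_tracks))
        write_track_csv(run$valid_tracks, file.path(out_dir, paste0(stem, "_Tracks.csv")))
      if (overlay) {
        st <- if (!is.null(run$shifts)) stack else stack  # stack already aligned inside run
        try(write_overlay_video(stack, file.path(out_dir, paste0(stem, "_Valid_tracks.tif")),
                                segmentations = run$segmentations,
                                tracks = run$valid_tracks), silent = TRUE)
      }
      if (plots) try(write_plots(run, out_dir, prefix = stem), silent = TRUE)
      logline("OK %s: %d tracks", v, dplyr::n_distinct(run$tracks$track))
      run
    }, error = function(e) e)
    if (inherits(res, "error")) {
      logline("FAILED %s: %s", v, conditionMessage(res))
      fails[[v]] <- tibble(video = v, error = conditionMessage(res))
    } else {
      runs[[stem]] <- res
      rows[[stem]] <- dplyr::bind_cols(tibble(video = v), glance(res))
    }
  }
  summary <- dplyr::bind_rows(rows)
  if (nrow(summary))
    write.csv(summary, file.path(base_dir, "phasetrack_Overall_summary.csv"), row.names = FALSE)
  logline("Batch done: %d ok, %d failed", length(runs), length(fails))
  list(summary = summary, runs = runs,
       failures = dplyr::bind_rows(fails), log = log_path)
}
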