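# Migration measures per track, per time step and per video.

#' Per-track migration metrics
#'
#' For every track with at least 2 observations: number of steps, duration
#' (minutes), mean step velocity (accumulated distance / duration),
#' accumulated distance (sum of step lengths), Euclidean distance
#' (start-to-end straight line), Euclidean velocity, directness
#' (Euclidean / accumulated, 1 for straight-line motion) and the forward
#' migration indices `fmi_x`, `fmi_y` (signed net axis displacement /
#' accumulated distance; image axes, y downward). Perfectly static tracks
#' (zero accumulated distance) report `NA` for directness and FMI rather
#' than zero.
#'
#' @param tracks A `pt_tracks` tibble.
#' @param dt Frame interval, minutes (taken from the tracks when attached).
#' @return A tibble with one row per track: `track`, `n_steps`,
#'   `duration`, `mean_step_velocity`, `accumulated_distance`,
#'   `euclidean_distance`, `euclidean_velocity`, `directness`, `fmi_x`,
#'   `fmi_y`, `start_x`, `start_y`.
#' @export
#' @examples
#' tr <- tibble::tibble(track = 1, frame = 1:5,
#'                      x = c(0, 5, 10, 15, 20), y = 0, repaired = FALSE)
#' track_metrics(tr, dt = 10)
track_metrics <- function(tracks, dt = NULL) {
  dt <- tracks_dt(tracks, dt)
  tracks |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::group_by(.data$track) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::summarise(
      n_steps = dplyr::n() - 1L,
      duration = .data$n_steps * dt,
      accumulated_distance = sum(hypot(diff(.data$x), diff(.data$y))),
      euclidean_distance = hypot(.data$x[dplyr::n()] - .data$x[1],
                                 .data$y[dplyr::n()] - .data$y[1]),
      net_dx = .data$x[dplyr::n()] - .data$x[1],
      net_dy = .data$y[dplyr::n()] - .data$y[1],
      start_x = .data$x[1],
      start_y = .data$y[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_step_velocity = .data$accumulated_distance / .data$duration,
      euclidean_velocity = .data$euclidean_distance / .data$duration,
      directness = dplyr::if_else(.data$accumulated_distance > 0,
                                  .data$euclidean_distance / .data$accumulated_distance,
                                  NA_real_),
      fmi_x = dplyr::if_else(.data$accumulated_distance > 0,
                             .data$net_dx / .data$accumulated_distance, NA_real_),
      fmi_y = dplyr::if_else(.data$accumulated_distance > 0,
                             .data$net_dy / .data$accumulated_distance, NA_real_)
    ) |>
    dplyr::select("track", "n_steps", "duration", "mean_step_velocity",
                  "accumulated_distance", "euclidean_distance",
                  "euclidean_velocity", "directness", "fmi_x", "fmi_y",
                  "start_x", "start_y")
}

#' Wound-healing sign convention for FMIy
#'
#' In a horizontal wound-healing assay cells advance into the cell-free
#' band from above and below. The wound midline is taken as the mean y of
#' all track starting points; `fmi_y` of tracks starting below the midline
#' is sign-flipped, so positive `fmi_y` always means motion INTO the wound.
#'
#' @param metrics Output of [track_metrics()] (needs `start_y`, `fmi_y`).
#' @param midline Wound midline y (micrometres); default mean of
#'   `start_y`.
#' @return `metrics` with signed `fmi_y` and a `start_side` column
#'   (`"top"`/`"bottom"`).
#' @export
wound_signed_fmi <- function(metrics, midline = NULL) {
  midline <- midline %||% mean(metrics$start_y)
  metrics |>
    dplyr::mutate(
      start_side = dplyr::if_else(.data$start_y <= midline, "top", "bottom"),
      fmi_y = dplyr::if_else(.data$start_side == "bottom", -.data$fmi_y, .data$fmi_y)
    )
}

#' Mean velocity over time
#'
#' For every consecutive frame pair, the mean step velocity over all
#' valid-track steps present in that pair, the number of such steps, and
#' the velocity-sum-per-cell misalignment diagnostic (from the matched
#' displacement vectors recorded during linking when available, else from
#' the track steps themselves). Frame pairs with no steps report `NA`.
#'
#' @param tracks A `pt_tracks` tibble (normally after
#'   [filter_valid_tracks()]).
#' @param dt Frame interval, minutes.
#' @return A tibble: `step` (index of the later frame), `time_min`, `n`,
#'   `mean_velocity`, `velocity_sum_per_cell`.
#' @export
mean_velocity_over_time <- function(tracks, dt = NULL) {
  dt <- tracks_dt(tracks, dt)
  steps <- tracks |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::group_by(.data$track) |>
    dplyr::mutate(dx = .data$x - dplyr::lag(.data$x),
                  dy = .data$y - dplyr::lag(.data$y)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx))
  frames <- sort(unique(tracks$frame))
  if (length(frames) < 2L) stopf("Need at least 2 frames of observations")
  all_steps <- tibble(step = frames[-1])
  per <- steps |>
    dplyr::group_by(step = .data$frame) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_velocity = mean(hypot(.data$dx, .data$dy)) / dt,
                     .groups = "drop")
  vs <- attr(tracks, "step_displacements")
  if (is.null(vs) || nrow(vs) == 0L) vs <- dplyr::select(steps, frame = "frame", "dx", "dy")
  vsum <- vs |>
    dplyr::group_by(step = .data$frame) |>
    dplyr::summarise(velocity_sum_per_cell = hypot(mean(.data$dx), mean(.data$dy)) / dt,
                     .groups = "drop")
  all_steps |>
    dplyr::left_join(per, by = "step") |>
    dplyr::left_join(vsum, by = "step") |>
    dplyr::mutate(time_min = (.data$step - 1) * dt, .after = "step")
}

# ---- histogram distributions (shared by velocity and distance) -----------

make_distribution <- function(values, bin_width, fit_halfwidth = 2L) {
  values <- values[is.finite(values)]
  if (!length(values)) stopf("No finite values to build a distribution from")
  bin <- floor(values / bin_width)
  bins <- seq.int(0L, max(bin))
  counts <- tabulate(bin + 1L, nbins = length(bins))
  mids <- (bins + 0.5) * bin_width
  pct <- 100 * counts / sum(counts)
  cum <- cumsum(pct)
  peak <- which.max(counts)
  lo <- peak - fit_halfwidth; hi <- peak + fit_halfwidth
  if (lo < 1L || hi > length(bins) || length(bins) < 2L * fit_halfwidth + 1L) {
    warnf("Distribution peak at the histogram edge; mode falls back to the peak-bin centre")
    mode <- mids[peak]
  } else {
    mode <- parabola_vertex(mids[lo:hi], counts[lo:hi])
    if (!is.finite(mode)) mode <- mids[peak]
  }
  # median by linear interpolation within the median bin
  mbin <- which(cum >= 50)[1]
  below <- if (mbin == 1L) 0 else cum[mbin - 1L]
  med <- (bins[mbin] + (50 - below) / pct[mbin]) * bin_width
  structure(list(
    bins = tibble(bin_mid = mids, count = counts, pct = pct, cum_pct = cum),
    bin_width = bin_width,
    mode = mode, median = med, mean = mean(values), n = length(values)
  ), class = "pt_distribution")
}

#' @export
print.pt_distribution <- function(x, ...) {
  cat(sprintf("<phasetrack distribution: n = %d, bin width %g; mode %.4g, median %.4g, mean %.4g>\n",
              x$n, x$bin_width, x$mode, x$median, x$mean))
  invisible(x)
}

#' Velocity distribution with parabola-fitted mode
#'
#' Histograms per-step velocities in fixed-width bins, normalises the
#' distribution to 100% and accumulates it. The mode is the vertex of a
#' least-squares parabola through the peak bin and its two neighbours on
#' each side (5 bins); the median is linearly interpolated within the
#' median bin. A population mode/median is less sensitive to a few very
#' fast cells than the mean.
#'
#' @param velocities Per-step velocities, micrometres/minute.
#' @param bin_width Histogram bin width, micrometres/minute.
#' @return A `pt_distribution` object (fields `bins`, `mode`, `median`,
#'   `mean`, `n`).
#' @export
velocity_distribution <- function(velocities, bin_width = 0.05) {
  make_distribution(velocities, bin_width)
}

#' Step velocities of a track set
#'
#' @param tracks A `pt_tracks` tibble.
#' @param dt Frame interval, minutes.
#' @return Vector of per-step velocities (micrometres/minute) over all
#'   tracks.
#' @export
step_velocities <- function(tracks, dt = NULL) {
  dt <- tracks_dt(tracks, dt)
  tracks |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::group_by(.data$track) |>
    dplyr::reframe(v = hypot(diff(.data$x), diff(.data$y)) / dt) |>
    dplyr::pull(.data$v)
}

#' Cell counts over time
#'
#' Identified-cell count per frame; with cells dividing this is the
#' proliferation read-out (a direct count is robust to cells changing
#' morphology, unlike confluence area).
#'
#' @param segmentations List of `pt_segmentation` objects, one per frame.
#' @return A tibble: `frame`, `n_candidates`, `n_identified`.
#' @export
count_cells_over_time <- function(segmentations) {
  tibble(
    frame = seq_along(segmentations),
    n_candidates = vapply(segmentations, function(s) s$n_candidates, 0L),
    n_identified = vapply(segmentations, function(s) s$n_identified, 0L)
  )
}

#' Translate tracks to a common origin
#'
#' Each track is translated so its first observation lies at (0, 0);
#' the standard way to compare migratory spread across tracks.
#'
#' @param tracks A `pt_tracks` tibble.
#' @return The translated tracks.
#' @export
common_origin <- function(tracks) {
  out <- tracks |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::group_by(.data$track) |>
    dplyr::mutate(x = .data$x - .data$x[1], y = .data$y - .data$y[1]) |>
    dplyr::ungroup()
  attributes(out)[c("dt", "step_displacements")] <-
    attributes(tracks)[c("dt", "step_displacements")]
  out
}
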