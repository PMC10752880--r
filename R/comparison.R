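# Cross-method trajectory comparison: track matching, gold-truth
# construction, point-to-point distance distributions, velocity agreement.
#
# The interchange schema is a plain table with columns
# track_id, frame, x_um, y_um (micrometres, shared coordinate frame), so
# tracks exported by any tracker can be compared.

.as_track_table <- function(x) {
  nm <- names(x)
  if (all(c("track_id", "frame", "x_um", "y_um") %in% nm)) {
    out <- list(track_id = x$track_id, frame = x$frame, x = x$x_um, y = x$y_um)
  } else if (all(c("track_id", "frame", "x", "y") %in% nm)) {
    out <- list(track_id = x$track_id, frame = x$frame, x = x$x, y = x$y)
  } else if (all(c("track", "frame", "x", "y") %in% nm)) {
    out <- list(track_id = x$track, frame = x$frame, x = x$x, y = x$y)
  } else {
    stopf("Track table needs columns track_id/frame/x_um/y_um (or track/frame/x/y)")
  }
  tibble::new_tibble(out, nrow = length(out$track_id))
}

#' Match two track sets by starting position
#'
#' Tracks whose first positions lie closer than `threshold` are considered
#' to describe the same cell. Matching is greedy by ascending
#' first-position distance, one-to-one, with the same deterministic
#' tie-break as the cell linker.
#'
#' @param tracks_a,tracks_b Track tables (columns `track_id`, `frame`,
#'   `x_um`, `y_um`, or `pt_tracks` tibbles) in the same micrometre
#'   coordinate frame.
#' @param threshold Maximum first-position distance, micrometres
#'   (default 15).
#' @return A list with `pairs` (tibble `track_a`, `track_b`,
#'   `start_distance`), `unmatched_a`, `unmatched_b` (track ids).
#' @export
match_track_sets <- function(tracks_a, tracks_b, threshold = 15) {
  a <- .as_track_table(tracks_a); b <- .as_track_table(tracks_b)
  starts <- function(d) d |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  sa <- starts(a); sb <- starts(b)
  m <- match_frames(
    cells_now = tibble(x = sb$x, y = sb$y, label = seq_len(nrow(sb))),
    cells_prev = tibble(x = sa$x, y = sa$y, label = seq_len(nrow(sa))),
    max_step = threshold)
  pairs <- tibble(track_a = sa$track_id[m$prev], track_b = sb$track_id[m$now],
                  start_distance = m$distance)
  list(pairs = pairs,
       unmatched_a = setdiff(sa$track_id, pairs$track_a),
       unmatched_b = setdiff(sb$track_id, pairs$track_b))
}

#' Aligned point-to-point distances of matched track pairs
#'
#' Aligns each matched pair on common frame indices and returns the
#' per-frame position distances.
#'
#' @param tracks_a,tracks_b Track tables (see [match_track_sets()]).
#' @param pairs Pair tibble from [match_track_sets()] (computed when
#'   omitted).
#' @param threshold Matching threshold passed on, micrometres.
#' @return A tibble: `track_a`, `track_b`, `frame`, `distance`
#'   (micrometres).
#' @export
pair_distances <- function(tracks_a, tracks_b, pairs = NULL, threshold = 15) {
  a <- .as_track_table(tracks_a); b <- .as_track_table(tracks_b)
  pairs <- pairs %||% match_track_sets(a, b, threshold)$pairs
  purrr::pmap_dfr(pairs[c("track_a", "track_b")], function(track_a, track_b) {
    pa <- a[a$track_id == track_a, ]; pb <- b[b$track_id == track_b, ]
    j <- dplyr::inner_join(pa, pb, by = "frame", suffix = c("_a", "_b"))
    tibble(track_a = track_a, track_b = track_b, frame = j$frame,
           distance = hypot(j$x_a - j$x_b, j$y_a - j$y_b))
  })
}

#' Consensus ("gold truth") positions from several annotators
#'
#' The consensus position of each cell at each frame is the arithmetic mean
#' over annotators; (cell, frame) points missing from any annotation are
#' excluded (and reported).
#'
#' @param annotations List of >= 2 track tables covering the same cells
#'   with shared `track_id` and `frame` keys.
#' @return A list with `positions` (tibble `track_id`, `frame`, `x_um`,
#'   `y_um`, `n_annotators`) and `n_excluded` (points not covered by all
#'   annotators).
#' @export
gold_truth_mean <- function(annotations) {
  stopifnot(length(annotations) >= 2L)
  k <- length(annotations)
  all <- dplyr::bind_rows(lapply(annotations, .as_track_table), .id = "annotator")
  agg <- all |>
    dplyr::group_by(.data$track_id, .data$frame) |>
    dplyr::summarise(x_um = mean(.data$x), y_um = mean(.data$y),
                     n_annotators = dplyr::n(), .groups = "drop")
  n_excluded <- sum(agg$n_annotators < k)
  if (n_excluded > 0)
    inform(sprintf("gold_truth_mean: %d (cell, frame) points missing from some annotators were excluded", n_excluded))
  list(positions = dplyr::filter(agg, .data$n_annotators == k),
       n_excluded = n_excluded)
}

#' Distance distribution of matched positions
#'
#' 1 um-binned, 100%-normalised distribution of point-to-point distances
#' with accumulated curve, parabola-vertex mode and interpolated median —
#' the summary used to compare trackers against a consensus annotation.
#'
#' @param distances Point-to-point distances (micrometres), e.g. the
#'   `distance` column of [pair_distances()].
#' @param bin_width Bin width, micrometres (default 1).
#' @return A `pt_distribution` object.
#' @export
distance_distribution <- function(distances, bin_width = 1) {
  make_distribution(distances, bin_width)
}

#' Fraction of distances above a cutoff
#'
#' Percentage of the distribution above `cutoff`, by linear interpolation
#' on the accumulated distribution (evaluated at bin upper edges).
#'
#' @param dist A `pt_distribution` from [distance_distribution()].
#' @param cutoff Cutoff distance in the distribution's units (default 10).
#' @return Percentage in `[0, 100]`.
#' @export
fraction_above <- function(dist, cutoff = 10) {
  w <- dist$bin_width
  edges <- c(0, dist$bins$bin_mid + w / 2)   # cum_pct at upper edges
  cum <- c(0, dist$bins$cum_pct)
  if (cutoff >= max(edges)) return(0)
  if (cutoff <= 0) return(100)
  100 - stats::approx(edges, cum, xout = cutoff, rule = 2)$y
}

#' Bland-Altman agreement of per-track mean velocities
#'
#' For each matched track pair, the difference of per-track mean step
#' velocities (method B minus method A); reports the mean difference
#' (bias) and the 95% limits of agreement (mean +/- 1.96 sd).
#'
#' @param tracks_a,tracks_b Track tables in micrometres.
#' @param dt Frame interval, minutes.
#' @param pairs Optional pair tibble from [match_track_sets()].
#' @param threshold Matching threshold, micrometres.
#' @return A `pt_agreement` object: list with `differences` (tibble
#'   `track_a`, `track_b`, `mean_a`, `mean_b`, `mean_velocity`,
#'   `difference`), `bias`, `lower`, `upper`.
#' @export
velocity_agreement <- function(tracks_a, tracks_b, dt, pairs = NULL, threshold = 15) {
  a <- .as_track_table(tracks_a); b <- .as_track_table(tracks_b)
  pairs <- pairs %||% match_track_sets(a, b, threshold)$pairs
  if (nrow(pairs) < 2L) stopf("Need at least 2 matched track pairs for agreement limits")
  mv <- function(d) d |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(mean_v = mean(hypot(diff(.data$x), diff(.data$y))) / dt,
                     .groups = "drop")
  va <- mv(a); vb <- mv(b)
  df <- pairs |>
    dplyr::left_join(va, by = c(track_a = "track_id")) |>
    dplyr::rename(mean_a = "mean_v") |>
    dplyr::left_join(vb, by = c(track_b = "track_id")) |>
    dplyr::rename(mean_b = "mean_v") |>
    dplyr::mutate(mean_velocity = (.data$mean_a + .data$mean_b) / 2,
                  difference = .data$mean_b - .data$mean_a)
  s <- sd(df$difference)
  structure(list(differences = df,
                 bias = mean(df$difference),
                 lower = mean(df$difference) - 1.96 * s,
                 upper = mean(df$difference) + 1.96 * s),
            class = "pt_agreement")
}

#' @export
print.pt_agreement <- function(x, ...) {
  cat(sprintf("<phasetrack velocity agreement: %d pairs, bias %.4g um/min, limits [%.4g, %.4g]>\n",
              nrow(x$differences), x$bias, x$lower, x$upper))
  invisible(x)
}

#' Write / read the track interchange CSV
#'
#' Plain CSV with columns `track_id`, `frame`, `x_um`, `y_um` (and
#' `repaired` when available), locale-independent decimal point.
#'
#' @param tracks A `pt_tracks` tibble or track table.
#' @param path CSV path.
#' @return `path` invisibly; `read_track_csv()` returns a tibble.
#' @export
write_track_csv <- function(tracks, path) {
  tt <- .as_track_table(tracks)
  out <- data.frame(track_id = tt$track_id, frame = tt$frame,
                    x_um = tt$x, y_um = tt$y)
  if ("repaired" %in% names(tracks)) out$repaired <- tracks$repaired
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  as_tibble(read.csv(path))
}
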