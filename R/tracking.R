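# Linking identified cells into tracks.
#
# Greedy nearest-neighbour matching: candidate pairs within the maximum
# step are sorted by displacement and accepted smallest-first (the cells
# that moved the least are the most certain matches). Cells missed in
# exactly one frame are recovered by a two-frame gap repair that inserts a
# midpoint observation; cells unmatched for two consecutive frames end
# their track, and unmatched detections start new ones.

#' Match cells between two frames
#'
#' All pairs with distance <= `max_step` are sorted ascending by distance
#' and accepted greedily while both cells are free. Ties break
#' deterministically on the smaller previous-cell label, then the smaller
#' current-cell label.
#'
#' @param cells_now,cells_prev Data frames with columns `x`, `y`
#'   (micrometres) and optionally `label` (defaults to row number).
#' @param max_step Longest allowed cell displacement between the frames,
#'   micrometres (highest cell velocity x frame interval).
#' @return A tibble with one row per accepted match: `prev`, `now` (row
#'   indices into the inputs) and `distance` (micrometres).
#' @export
match_frames <- function(cells_now, cells_prev, max_step) {
  n_now <- nrow(cells_now); n_prev <- nrow(cells_prev)
  if (n_now == 0L || n_prev == 0L)
    return(tibble(prev = integer(), now = integer(), distance = numeric()))
  lab_now <- if ("label" %in% names(cells_now)) cells_now$label else seq_len(n_now)
  lab_prev <- if ("label" %in% names(cells_prev)) cells_prev$label else seq_len(n_prev)
  d <- sqrt(outer(cells_prev$x, cells_now$x, "-")^2 +
            outer(cells_prev$y, cells_now$y, "-")^2)
  ok <- which(d <= max_step, arr.ind = TRUE)
  if (nrow(ok) == 0L)
    return(tibble(prev = integer(), now = integer(), distance = numeric()))
  dist <- d[ok]
  ord <- order(dist, lab_prev[ok[, 1]], lab_now[ok[, 2]])
  ok <- ok[ord, , drop = FALSE]; dist <- dist[ord]
  free_prev <- rep(TRUE, n_prev); free_now <- rep(TRUE, n_now)
  keep <- logical(nrow(ok))
  for (r in seq_len(nrow(ok))) {
    i <- ok[r, 1]; j <- ok[r, 2]
    if (free_prev[i] && free_now[j]) {
      keep[r] <- TRUE
      free_prev[i] <- FALSE; free_now[j] <- FALSE
    }
  }
  tibble(prev = as.integer(ok[keep, 1]), now = as.integer(ok[keep, 2]),
         distance = dist[keep])
}

#' Build tracks from per-frame segmentations
#'
#' Frame-by-frame greedy matching of identified cells, followed by gap
#' repair: a detection with no match one frame back is joined to the
#' closest track that ended two frames back (within `2 * max_step`), with a
#' midpoint observation inserted at the missing frame and flagged
#' `repaired`. Remaining unmatched detections start new tracks; tracks
#' unmatched for two consecutive frames end. After a cell division the
#' nearest daughter continues the track and the other starts a new one —
#' an emergent property of distance matching, no lineage is recorded.
#'
#' @param segmentations List of `pt_segmentation` (one per frame) from
#'   [segment_frame()], or a list of data frames of identified cells with
#'   columns `x`, `y` and optionally `equivalent_diameter`, `label`.
#' @param settings A [settings()] object (`highest_cell_velocity`,
#'   `time_between_images`/stack `dt`).
#' @param dt Frame interval in minutes (defaults to
#'   `settings$time_between_images`).
#' @return A `pt_tracks` tibble: `track`, `frame`, `x`, `y`,
#'   `equivalent_diameter`, `repaired`; attributes `dt` (minutes) and
#'   `step_displacements` (tibble of matched per-step displacement vectors
#'   `frame`, `dx`, `dy` in micrometres, used for the velocity-sum-per-cell
#'   diagnostic).
#' @export
build_tracks <- function(segmentations, settings = default_settings(), dt = NULL) {
  dt <- dt %||% settings$time_between_images
  max_step <- settings$highest_cell_velocity * dt
  cells <- lapply(segmentations, function(s) {
    if (inherits(s, "pt_segmentation")) {
      r <- s$regions[s$regions$status == "identified", , drop = FALSE]
      tibble(x = r$x, y = r$y,
             equivalent_diameter = r$equivalent_diameter,
             label = r$label)
    } else {
      tibble(x = s$x, y = s$y,
             equivalent_diameter = if ("equivalent_diameter" %in% names(s))
               s$equivalent_diameter else rep(NA_real_, nrow(s)),
             label = if ("label" %in% names(s)) s$label else seq_len(nrow(s)))
    }
  })
  n_frames <- length(cells)
  if (n_frames < 2L) stopf("Need at least 2 segmented frames to build tracks")

  tracks <- list()       # each: list(frame =, x =, y =, d =, rep =)
  last_frame <- integer(0)
  new_track <- function(t, row) {
    tracks[[length(tracks) + 1L]] <<- list(
      frame = t, x = row$x, y = row$y, d = row$equivalent_diameter, rep = FALSE)
    last_frame[length(tracks)] <<- t
  }
  append_obs <- function(id, t, row, repaired_mid = NULL) {
    tr <- tracks[[id]]
    if (!is.null(repaired_mid)) {
      tr$frame <- c(tr$frame, t - 1L); tr$x <- c(tr$x, repaired_mid[1])
      tr$y <- c(tr$y, repaired_mid[2]); tr$d <- c(tr$d, NA_real_); tr$rep <- c(tr$rep, TRUE)
    }
    tr$frame <- c(tr$frame, t); tr$x <- c(tr$x, row$x); tr$y <- c(tr$y, row$y)
    tr$d <- c(tr$d, row$equivalent_diameter); tr$rep <- c(tr$rep, FALSE)
    tracks[[id]] <<- tr
    last_frame[id] <<- t
  }
  for (r in seq_len(nrow(cells[[1]]))) new_track(1L, cells[[1]][r, ])

  disp <- vector("list", n_frames)
  for (t in seq.int(2L, n_frames)) {
    now <- cells[[t]]
    ext_ids <- which(last_frame == t - 1L)
    prev_pos <- tibble(
      x = vapply(ext_ids, function(i) tail(tracks[[i]]$x, 1), 0),
      y = vapply(ext_ids, function(i) tail(tracks[[i]]$y, 1), 0),
      label = ext_ids)
    m <- match_frames(now, prev_pos, max_step)
    matched_now <- m$now
    for (r in seq_len(nrow(m))) {
      append_obs(ext_ids[m$prev[r]], t, now[m$now[r], ])
    }
    if (nrow(m)) {
      disp[[t]] <- tibble(
        frame = t,
        dx = now$x[m$now] - prev_pos$x[m$prev],
        dy = now$y[m$now] - prev_pos$y[m$prev])
    }
    # gap repair against tracks that ended two frames back
    orphan <- setdiff(seq_len(nrow(now)), matched_now)
    stale_ids <- which(last_frame == t - 2L)
    if (length(orphan) && length(stale_ids)) {
      stale_pos <- tibble(
        x = vapply(stale_ids, function(i) tail(tracks[[i]]$x, 1), 0),
        y = vapply(stale_ids, function(i) tail(tracks[[i]]$y, 1), 0),
        label = stale_ids)
      mr <- match_frames(now[orphan, , drop = FALSE], stale_pos, 2 * max_step)
      for (r in seq_len(nrow(mr))) {
        id <- stale_ids[mr$prev[r]]
        row <- now[orphan[mr$now[r]], ]
        mid <- c((tail(tracks[[id]]$x, 1) + row$x) / 2,
                 (tail(tracks[[id]]$y, 1) + row$y) / 2)
        append_obs(id, t, row, repaired_mid = mid)
      }
      matched_now <- c(matched_now, orphan[mr$now])
    }
    for (r in setdiff(seq_len(nrow(now)), matched_now)) new_track(t, now[r, ])
  }

  out <- dplyr::bind_rows(lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    tibble(track = i, frame = tr$frame, x = tr$x, y = tr$y,
           equivalent_diameter = tr$d, repaired = tr$rep)
  }))
  out <- dplyr::arrange(out, .data$track, .data$frame)
  as_pt_tracks(out, dt = dt,
               step_displacements = dplyr::bind_rows(disp))
}

as_pt_tracks <- function(df, dt, step_displacements = NULL) {
  out <- as_tibble(df)
  attr(out, "dt") <- dt
  attr(out, "step_displacements") <- step_displacements
  class(out) <- c("pt_tracks", class(out))
  out
}

tracks_dt <- function(tracks, dt = NULL) {
  dt <- dt %||% attr(tracks, "dt")
  if (is.null(dt)) stopf("Frame interval 'dt' is neither supplied nor attached to the tracks")
  dt
}

#' Smooth track coordinates
#'
#' Per iteration every interior position is replaced by the
#' (1/4, 1/2, 1/4)-weighted average of its predecessor, itself and its
#' successor; the start and end points of each track remain fixed. Smoothing
#' shrinks the small back-and-forth jumps of the detected nucleus centre
#' while preserving genuine net movement.
#'
#' @param tracks A `pt_tracks` tibble (or any tibble with `track`, `frame`,
#'   `x`, `y`).
#' @param iterations Number of smoothing passes (0 = identity).
#' @return The tracks with smoothed `x`, `y`.
#' @export
smooth_tracks <- function(tracks, iterations = 1L) {
  if (iterations == 0L) return(tracks)
  sm1 <- function(v) {
    n <- length(v)
    if (n < 3L) return(v)
    inner <- 0.25 * v[1:(n - 2)] + 0.5 * v[2:(n - 1)] + 0.25 * v[3:n]
    c(v[1], inner, v[n])
  }
  ord <- order(tracks$track, tracks$frame)
  x <- tracks$x[ord]; y <- tracks$y[ord]
  idx <- split(seq_along(ord), tracks$track[ord])
  for (ii in idx) {
    xi <- x[ii]; yi <- y[ii]
    for (k in seq_len(iterations)) { xi <- sm1(xi); yi <- sm1(yi) }
    x[ii] <- xi; y[ii] <- yi
  }
  tracks$x[ord] <- x; tracks$y[ord] <- y
  tracks
}

#' Keep only valid tracks
#'
#' A valid track has at least `shortest_cell_track` observations; only
#' valid tracks enter the migration metrics and overlays.
#'
#' @param tracks A `pt_tracks` tibble.
#' @param shortest_cell_track Minimum number of observations (>= 2).
#' @return The filtered tracks.
#' @export
filter_valid_tracks <- function(tracks, shortest_cell_track = 5L) {
  stopifnot(shortest_cell_track >= 2)
  keep <- tracks |>
    dplyr::count(.data$track) |>
    dplyr::filter(.data$n >= shortest_cell_track) |>
    dplyr::pull(.data$track)
  out <- dplyr::filter(tracks, .data$track %in% keep)
  attributes(out)[c("dt", "step_displacements")] <-
    attributes(tracks)[c("dt", "step_displacements")]
  class(out) <- class(tracks)
  out
}
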