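# Seeded synthetic phase-contrast-like videos with exact ground truth.
#
# Emulates the features segmentation and tracking rely on in incubator
# phase-contrast imagery: a bright background, darker elliptical nuclei,
# optional static cross / speckle artefacts, global frame jitter, pixel
# noise, and cells moving by drift + Brownian steps with optional
# divisions and a wound geometry. Realism stops where the segmentation
# assumptions stop: there is no optical physics beyond an optional
# cosmetic halo ring.

#' Specify a synthetic video
#'
#' All lengths in micrometres, times in minutes. The defaults describe a
#' sparsely seeded random-migration well: 0.645 um pixels, 10-min frame
#' interval, nuclei around 16 um equivalent diameter rendered 60 grey
#' levels darker than a level-150 background, Brownian motion with a 2 um
#' per-step component standard deviation, and iid pixel noise (sd 3).
#'
#' @param width_px,height_px Frame size, pixels.
#' @param pixel_size Micrometres per pixel.
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval, minutes.
#' @param n_cells Initial cell count.
#' @param diameter_mean,diameter_sd Nucleus equivalent diameter, um.
#' @param depression Grey levels the nucleus centre lies below background.
#' @param background Background grey level.
#' @param noise_sd Iid pixel noise standard deviation, grey levels.
#' @param sigma_step Brownian per-step displacement sd per component, um.
#' @param drift Drift vector per step `(dx, dy)`, um.
#' @param jitter Optional `n_frames x 2` matrix of global frame shifts
#'   (pixels, applied to the rendered frame; ground truth stores
#'   pre-jitter positions). Default: no jitter.
#' @param cross_artifact Render a static dark plate-etching cross.
#' @param speckle_density Static dark speckles (collagen-like) per um^2.
#' @param division_prob Per-cell per-frame division probability.
#' @param wound Optional wound geometry:
#'   `list(half_width = <um>, inflow = <um/step>)` — a horizontal cell-free
#'   band at mid-height; cells drift toward the band at `inflow` um/step.
#' @param halo Amplitude of a cosmetic bright halo ring (grey levels).
#' @param min_spacing Minimum initial centre-to-centre spacing, um
#'   (default 2 diameters).
#' @param seed Integer seed; the same spec generates bit-identical videos.
#' @return A `pt_synthetic_spec` object.
#' @export
synthetic_spec <- function(width_px = 512L, height_px = 512L, pixel_size = 0.645,
                           n_frames = 20L, dt = 10, n_cells = 50L,
                           diameter_mean = 16, diameter_sd = 1.5,
                           depression = 60, background = 150, noise_sd = 3,
                           sigma_step = 2, drift = c(0, 0), jitter = NULL,
                           cross_artifact = FALSE, speckle_density = 0,
                           division_prob = 0, wound = NULL, halo = 0,
                           min_spacing = 2 * diameter_mean, seed = 1L) {
  stopifnot(n_frames >= 2L, n_cells >= 1L, background - depression >= 0,
            sigma_step >= 0, noise_sd >= 0, diameter_mean > 0,
            diameter_mean < min(width_px, height_px) * pixel_size)
  if (!is.null(jitter)) {
    jitter <- as.matrix(jitter)
    stopifnot(nrow(jitter) == n_frames, ncol(jitter) == 2L)
  }
  structure(as.list(environment()), class = "pt_synthetic_spec")
}

#' @export
print.pt_synthetic_spec <- function(x, ...) {
  cat(sprintf("<phasetrack synthetic spec: %d cells, %d frames %dx%d px, sigma %g um/step, seed %d>\n",
              x$n_cells, x$n_frames, x$width_px, x$height_px, x$sigma_step, x$seed))
  invisible(x)
}

# place n points with minimal spacing by rejection sampling
.place_cells <- function(n, wu, hu, margin, min_spacing, wound = NULL) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 20000L * n)
      stopf("Cannot place %d cells without initial overlap; frame too crowded", n)
    x <- runif(1, margin, wu - margin); y <- runif(1, margin, hu - margin)
    if (!is.null(wound) && abs(y - hu / 2) < wound$half_width) next
    if (length(xs) && min(hypot(xs - x, ys - y)) < min_spacing) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic video with ground truth
#'
#' Renders cells as Gaussian-profile dark ellipses on a bright background;
#' positions evolve by drift + Brownian steps with reflection at the
#' borders; divisions split a cell into two daughters placed 0.6 diameters
#' to each side; global jitter is applied to whole frames AFTER rendering;
#' cross/speckle artefacts are composited; pixel noise is added last. The
#' ground truth records pre-jitter ("world") positions.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `stack` (a `pt_stack`) and `truth`, a tibble of true
#'   per-frame cell centres: `cell`, `frame`, `x`, `y` (um), `diameter`,
#'   `parent` (NA for founder cells).
#' @export
generate_video <- function(spec) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  px <- spec$pixel_size
  W <- spec$width_px; H <- spec$height_px
  wu <- W * px; hu <- H * px
  margin <- spec$diameter_mean
  pos <- .place_cells(spec$n_cells, wu, hu, margin, spec$min_spacing, spec$wound)
  n0 <- nrow(pos)
  diam <- pmax(spec$diameter_mean / 3,
               rnorm(n0, spec$diameter_mean, spec$diameter_sd))
  aspect <- runif(n0, 0.85, 1)
  angle <- runif(n0, 0, pi)
  cells <- tibble(cell = seq_len(n0), x = pos[, 1], y = pos[, 2],
                  diameter = diam, aspect = aspect, angle = angle,
                  parent = NA_integer_, alive = TRUE)
  next_id <- n0 + 1L

  # static artefact fields (composited before noise)
  artefact <- matrix(0, H, W)
  if (spec$cross_artifact) {
    band_px <- round(40 / px)  # 40 um wide: wider than any cell
    rc <- round(H / 2); cc <- round(W / 2)
    rows <- clamp(seq.int(rc - band_px %/% 2, rc + band_px %/% 2), 1, H)
    cols <- clamp(seq.int(cc - band_px %/% 2, cc + band_px %/% 2), 1, W)
    artefact[rows, ] <- artefact[rows, ] - 25
    artefact[, cols] <- pmin(artefact[, cols], -25)
  }
  if (spec$speckle_density > 0) {
    n_sp <- stats::rpois(1, spec$speckle_density * wu * hu)
    if (n_sp > 0) {
      sr <- sample.int(H, n_sp, replace = TRUE)
      sc <- sample.int(W, n_sp, replace = TRUE)
      for (i in seq_len(n_sp)) {
        rr <- clamp(sr[i] + (-1:1), 1, H); cc2 <- clamp(sc[i] + (-1:1), 1, W)
        artefact[rr, cc2] <- artefact[rr, cc2] - 40
      }
    }
  }

  render <- function(cells) {
    # nuclei are opaque objects: where two overlap the darkest wins,
    # they do not darken additively
    D <- matrix(0, H, W)
    alive <- cells[cells$alive, , drop = FALSE]
    for (i in seq_len(nrow(alive))) {
      r0 <- alive$diameter[i] / 2 / px          # px
      a <- r0 / sqrt(alive$aspect[i]); b <- r0 * sqrt(alive$aspect[i])
      th <- alive$angle[i]
      cx <- alive$x[i] / px; cy <- alive$y[i] / px   # 0-based px centre
      ext <- ceiling(2.2 * a)
      cols <- seq.int(max(0L, floor(cx) - ext), min(W - 1L, ceiling(cx) + ext))
      rows <- seq.int(max(0L, floor(cy) - ext), min(H - 1L, ceiling(cy) + ext))
      dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
      dy <- matrix(rows - cy, length(rows), length(cols))
      xr <- dx * cos(th) + dy * sin(th)
      yr <- -dx * sin(th) + dy * cos(th)
      rho2 <- (xr / a)^2 + (yr / b)^2
      depth <- spec$depression * exp(-rho2^3)
      if (spec$halo > 0) depth <- depth - spec$halo * exp(-((sqrt(rho2) - 1.4)^2) / 0.08)
      D[rows + 1L, cols + 1L] <- pmax(D[rows + 1L, cols + 1L], depth)
    }
    matrix(spec$background, H, W) + artefact - D
  }

  reflect <- function(v, lo, hi) {
    v <- ifelse(v < lo, 2 * lo - v, v)
    ifelse(v > hi, 2 * hi - v, v)
  }

  # nuclear exclusion: nuclei cannot overlap, so pairs closer than 1.1 x
  # their mean diameter are pushed apart (a few relaxation sweeps)
  relax <- function(cells) {
    alive <- which(cells$alive)
    if (length(alive) < 2L) return(cells)
    for (sweep in 1:3) {
      moved <- FALSE
      for (ii in seq_along(alive)) {
        i <- alive[ii]
        d <- hypot(cells$x[alive] - cells$x[i], cells$y[alive] - cells$y[i])
        min_sep <- 1.1 * (cells$diameter[alive] + cells$diameter[i]) / 2
        close <- which(d > 0 & d < min_sep)
        for (jj in close) {
          j <- alive[jj]
          push <- (min_sep[jj] - d[jj]) / 2
          ux <- (cells$x[j] - cells$x[i]) / d[jj]
          uy <- (cells$y[j] - cells$y[i]) / d[jj]
          cells$x[i] <- clamp(cells$x[i] - push * ux, margin, wu - margin)
          cells$y[i] <- clamp(cells$y[i] - push * uy, margin, hu - margin)
          cells$x[j] <- clamp(cells$x[j] + push * ux, margin, wu - margin)
          cells$y[j] <- clamp(cells$y[j] + push * uy, margin, hu - margin)
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    cells
  }

  frames <- vector("list", spec$n_frames)
  truth <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    if (t > 1L) {
      alive <- which(cells$alive)
      n_alive <- length(alive)
      drift <- spec$drift
      step_x <- drift[1] + rnorm(n_alive, 0, spec$sigma_step)
      step_y <- drift[2] + rnorm(n_alive, 0, spec$sigma_step)
      if (!is.null(spec$wound) && spec$wound$inflow != 0) {
        toward <- ifelse(cells$y[alive] < hu / 2, 1, -1)
        step_y <- step_y + toward * spec$wound$inflow
      }
      cells$x[alive] <- reflect(cells$x[alive] + step_x, margin, wu - margin)
      cells$y[alive] <- reflect(cells$y[alive] + step_y, margin, hu - margin)
      if (spec$division_prob > 0) {
        dividing <- alive[runif(n_alive) < spec$division_prob]
        for (i in dividing) {
          th <- runif(1, 0, 2 * pi)
          off <- 0.6 * cells$diameter[i]
          for (s in c(-1, 1)) {
            dx <- s * off * cos(th); dy <- s * off * sin(th)
            cells <- dplyr::bind_rows(cells, tibble(
              cell = next_id,
              x = clamp(cells$x[i] + dx, margin, wu - margin),
              y = clamp(cells$y[i] + dy, margin, hu - margin),
              diameter = cells$diameter[i], aspect = cells$aspect[i],
              angle = runif(1, 0, pi), parent = cells$cell[i], alive = TRUE))
            next_id <- next_id + 1L
          }
          cells$alive[i] <- FALSE
        }
      }
      cells <- relax(cells)
    }
    f <- render(cells)
    if (!is.null(spec$jitter)) f <- apply_fractional_shift(f, spec$jitter[t, 1], spec$jitter[t, 2])
    if (spec$noise_sd > 0) f <- f + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    frames[[t]] <- clamp(f, 0, 255)
    al <- cells[cells$alive, , drop = FALSE]
    truth[[t]] <- tibble(cell = al$cell, frame = t, x = al$x, y = al$y,
                         diameter = al$diameter, parent = al$parent)
  }
  list(stack = image_stack(frames, px, spec$dt),
       truth = dplyr::bind_rows(truth))
}

#' Evaluate tracking against ground truth
#'
#' Assigns every track observation to the nearest ground-truth cell within
#' `radius` in the same frame, then reports per-track identity switches
#' (changes of assigned truth id along a track), the position-error
#' distribution, and the fraction of truth cells recovered full-length by
#' a single track.
#'
#' @param tracks A `pt_tracks` tibble (same coordinate frame as the truth,
#'   i.e. tracks from a jitter-corrected video).
#' @param truth Ground-truth tibble from [generate_video()].
#' @param radius Association radius, micrometres.
#' @return A list with `per_track` (tibble `track`, `n_assigned`,
#'   `switches`), `n_switches`, `position_errors` (um), `errors`
#'   (a `pt_distribution` when enough points), and
#'   `fraction_full_length`.
#' @export
evaluate_tracking <- function(tracks, truth, radius = 10) {
  by_frame <- split(truth, truth$frame)
  assigned <- tracks |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::mutate(truth_cell = NA_integer_, error = NA_real_)
  for (i in seq_len(nrow(assigned))) {
    tf <- by_frame[[as.character(assigned$frame[i])]]
    if (is.null(tf) || nrow(tf) == 0L) next
    d <- hypot(tf$x - assigned$x[i], tf$y - assigned$y[i])
    j <- which.min(d)
    if (d[j] <= radius) {
      assigned$truth_cell[i] <- tf$cell[j]
      assigned$error[i] <- d[j]
    }
  }
  per_track <- assigned |>
    dplyr::group_by(.data$track) |>
    dplyr::summarise(
      n_assigned = sum(!is.na(.data$truth_cell)),
      switches = {
        ids <- .data$truth_cell[!is.na(.data$truth_cell)]
        if (length(ids) > 1L) sum(diff(ids) != 0L) else 0L
      },
      .groups = "drop")
  # a truth cell is fully recovered when one track covers all its frames
  alive_len <- truth |> dplyr::count(.data$cell, name = "alive")
  cover <- assigned |>
    dplyr::filter(!is.na(.data$truth_cell)) |>
    dplyr::count(.data$truth_cell, .data$track) |>
    dplyr::group_by(.data$truth_cell) |>
    dplyr::summarise(best = max(.data$n), .groups = "drop") |>
    dplyr::left_join(alive_len, by = c(truth_cell = "cell"))
  full <- sum(cover$best >= cover$alive)
  errs <- assigned$error[!is.na(assigned$error)]
  list(per_track = per_track,
       n_switches = sum(per_track$switches),
       position_errors = errs,
       errors = if (length(errs) >= 5L) tryCatch(distance_distribution(errs, bin_width = 0.5),
                                                 warning = function(w) NULL,
                                                 error = function(e) NULL) else NULL,
       fraction_full_length = full / nrow(alive_len))
}
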