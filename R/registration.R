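# Sub-pixel lateral frame registration.
#
# Consecutive frames from automated incubator microscopes are often displaced
# by a few pixels between revisits of the same well position. Tracking then
# sees a common apparent displacement of all cells, inflating velocities.
# Each frame is registered to its predecessor by an integer grid search that
# minimises the mean absolute grey difference on the overlap, refined to
# fractional pixels with a 1-D parabola through the cost profile in each
# axis, and resampled bilinearly.

#' Estimate the lateral shift between two frames
#'
#' Finds the (dx, dy), in fractional pixels, by which `moving` must be
#' shifted to look most similar to `reference`: integer search over
#' `[-max_search, max_search]^2` minimising the mean absolute grey
#' difference on the overlap region, then independent 1-D parabola
#' refinement through the cost at the optimum and its two neighbours in x
#' and in y.
#'
#' @param reference,moving Numeric grey matrices of identical dimensions.
#' @param max_search Search half-range in pixels (>= 1).
#' @param stride Pixel subsampling stride for cost evaluation (speed knob;
#'   1 = use every pixel).
#' @return A list with `dx`, `dy` (fractional pixels; positive x rightward,
#'   positive y downward), `cost` (cost at the integer optimum) and
#'   `at_bound` (TRUE when the optimum hit the search boundary, in which
#'   case no sub-pixel refinement is applied).
#' @export
estimate_pairwise_shift <- function(reference, moving, max_search = 20L, stride = 2L) {
  stopifnot(all(dim(reference) == dim(moving)), max_search >= 1)
  if (sd(reference) == 0 || sd(moving) == 0) {
    warnf("Flat frame in shift estimation; returning (0, 0)")
    return(list(dx = 0, dy = 0, cost = NA_real_, at_bound = FALSE))
  }
  H <- nrow(reference); W <- ncol(reference)
  s <- as.integer(max_search)
  offs <- seq.int(-s, s)
  cost <- matrix(NA_real_, length(offs), length(offs))  # [dy, dx]
  for (iy in seq_along(offs)) {
    dy <- offs[iy]
    rr <- seq.int(max(1L, 1L + dy), min(H, H + dy), by = stride)
    for (ix in seq_along(offs)) {
      dx <- offs[ix]
      cc <- seq.int(max(1L, 1L + dx), min(W, W + dx), by = stride)
      cost[iy, ix] <- mean(abs(reference[rr, cc] - moving[rr - dy, cc - dx]))
    }
  }
  best <- which(cost == min(cost), arr.ind = TRUE)[1, ]  # deterministic: first in column-major order
  iy <- best[[1]]; ix <- best[[2]]
  at_bound <- iy == 1L || iy == length(offs) || ix == 1L || ix == length(offs)
  dx <- as.numeric(offs[ix]); dy <- as.numeric(offs[iy])
  if (cost[iy, ix] == 0) {
    # perfect integer match: parabola refinement would only add boundary bias
  } else if (!at_bound) {
    refine <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (den <= 0) 0 else clamp(0.5 * (cm - cp) / den, -0.5, 0.5)
    }
    dx <- dx + refine(cost[iy, ix - 1L], cost[iy, ix], cost[iy, ix + 1L])
    dy <- dy + refine(cost[iy - 1L, ix], cost[iy, ix], cost[iy + 1L, ix])
  } else {
    warnf("Shift estimate (%g, %g) is on the search boundary; no sub-pixel refinement", dx, dy)
  }
  list(dx = dx, dy = dy, cost = cost[iy, ix], at_bound = at_bound)
}

#' Shift a frame by a fractional number of pixels
#'
#' Bilinear resampling; pixels shifted in from outside the frame are filled
#' by edge replication. Positive `dx` moves content rightward, positive `dy`
#' downward. The output has the same dimensions as the input.
#'
#' @param frame Numeric grey matrix.
#' @param dx,dy Shift in fractional pixels.
#' @return The shifted frame.
#' @export
apply_fractional_shift <- function(frame, dx, dy) {
  if (dx == 0 && dy == 0) return(frame)
  H <- nrow(frame); W <- ncol(frame)
  ys <- seq_len(H) - dy
  xs <- seq_len(W) - dx
  y0 <- clamp(floor(ys), 1, H); y1 <- clamp(y0 + 1, 1, H)
  x0 <- clamp(floor(xs), 1, W); x1 <- clamp(x0 + 1, 1, W)
  fy <- clamp(ys - floor(ys), 0, 1); fx <- clamp(xs - floor(xs), 0, 1)
  # separable gather: rows depend on y only, columns on x only
  f00 <- frame[y0, x0, drop = FALSE]; f01 <- frame[y0, x1, drop = FALSE]
  f10 <- frame[y1, x0, drop = FALSE]; f11 <- frame[y1, x1, drop = FALSE]
  wy <- matrix(fy, H, W); wx <- matrix(fx, H, W, byrow = TRUE)
  (1 - wy) * ((1 - wx) * f00 + wx * f01) + wy * ((1 - wx) * f10 + wx * f11)
}

#' Align an image stack to its first frame
#'
#' Estimates the pairwise shift of every frame relative to its predecessor
#' and applies the cumulative shift, so the whole series shares frame 1's
#' coordinate system. Crop margins (applied downstream) absorb the
#' edge-replicated borders.
#'
#' @param stack A `pt_stack`.
#' @param settings A [settings()] object (`max_shift_search` is used).
#' @return A list with `stack` (aligned `pt_stack`) and `shifts`, a tibble of
#'   per-frame shift records: `frame`, `dx`, `dy`, `cumulative_dx`,
#'   `cumulative_dy`, `cost`, `at_bound`.
#' @export
align_stack <- function(stack, settings = default_settings()) {
  n <- length(stack$frames)
  rec <- tibble(frame = seq_len(n), dx = 0, dy = 0,
                cumulative_dx = 0, cumulative_dy = 0,
                cost = NA_real_, at_bound = FALSE)
  frames <- stack$frames
  cum_dx <- 0; cum_dy <- 0
  for (k in seq.int(2L, n)) {
    est <- estimate_pairwise_shift(stack$frames[[k - 1L]], stack$frames[[k]],
                                   max_search = settings$max_shift_search)
    cum_dx <- cum_dx + est$dx
    cum_dy <- cum_dy + est$dy
    rec$dx[k] <- est$dx; rec$dy[k] <- est$dy
    rec$cumulative_dx[k] <- cum_dx; rec$cumulative_dy[k] <- cum_dy
    rec$cost[k] <- est$cost; rec$at_bound[k] <- est$at_bound
    frames[[k]] <- apply_fractional_shift(stack$frames[[k]], cum_dx, cum_dy)
  }
  list(stack = image_stack(frames, stack$pixel_size, stack$dt), shifts = rec)
}

#' Velocity sum per cell
#'
#' The magnitude of the mean displacement vector of all matched cells
#' between two consecutive frames, divided by the frame interval. Random
#' cell motion cancels in the vector mean, so values well above ~0.1 um/min
#' indicate residual global frame misalignment rather than migration.
#'
#' @param dx,dy Matched per-cell displacement components between the two
#'   frames, micrometres.
#' @param dt Frame interval, minutes.
#' @return Micrometres per minute; `NA` when there are no displacements.
#' @export
velocity_sum_per_cell <- function(dx, dy, dt) {
  if (length(dx) == 0L) return(NA_real_)
  hypot(mean(dx), mean(dy)) / dt
}
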