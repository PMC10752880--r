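# Segmentation: grey-level limit, candidate extraction, concavity cutting
# of touching cells, size gating.
#
# Phase-contrast nuclei appear as the darkest structures on a bright
# background, so after wide Gaussian smoothing a single grey-level limit
# separates candidate cells from background. Touching cells merge into one
# component; a boundary-curvature routine cuts such regions at paired
# concave "neck" points.

#' Determine the grey-level limit for segmentation
#'
#' Manual mode (`segmentation_limit` a negative number z):
#' `limit = mean(grey) + z * sd(grey)` over the frame. Auto mode
#' (`"auto"`): the background is modelled from the dominant peak of the
#' grey histogram; since cells only darken pixels, the peak half-width is
#' estimated from the bright side of the peak, and
#' `limit = mu_bg - k * sigma_bg`.
#'
#' @param frame Smoothed numeric grey matrix.
#' @param segmentation_limit `"auto"` or a negative z-score.
#' @param k Background-peak z cut used in auto mode (default 3).
#' @return The grey-level limit (scalar).
#' @export
#' @examples
#' f <- matrix(rnorm(1e4, 150, 20), 100)
#' determine_grey_limit(f, -1.5)  # ~ 150 - 1.5 * 20
determine_grey_limit <- function(frame, segmentation_limit = "auto", k = 3) {
  s <- sd(frame)
  if (s == 0) stopf("Cannot determine a segmentation limit: frame has no contrast")
  if (is.numeric(segmentation_limit)) {
    return(mean(frame) + segmentation_limit * s)
  }
  g <- clamp(round(frame), 0, 255)
  h <- tabulate(g + 1L, nbins = 256L)      # h[i] = count of grey level i - 1
  peak <- which.max(h)
  mu_bg <- peak - 1
  # half-width at half maximum on the bright side of the background peak
  half <- h[peak] / 2
  bright <- h[seq.int(peak, 256L)]
  below <- which(bright < half)
  if (length(below) == 0L) {
    hwhm <- 256 - peak
  } else {
    j <- below[1]                           # first bin under half max
    if (j == 1L) {
      hwhm <- 0.5
    } else {
      # linear interpolation between bins j-1 and j for the half crossing
      hwhm <- (j - 2) + (bright[j - 1L] - half) / (bright[j - 1L] - bright[j])
    }
  }
  sigma_bg <- max(hwhm / sqrt(2 * log(2)), 0.5)
  mu_bg - k * sigma_bg
}

# ---- connected components ------------------------------------------------

# 8-connected labelling: EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass.
label_components <- function(mask) {
  storage.mode(mask) <- "integer"
  lbl <- EBImage::bwlabel(mask)
  n <- max(lbl)
  if (n <= 1L) return(matrix(as.integer(lbl), nrow(mask), ncol(mask)))
  H <- nrow(lbl); W <- ncol(lbl)
  a1 <- lbl[-H, -W]; b1 <- lbl[-1, -1]     # NW-SE diagonal pairs
  a2 <- lbl[-1, -W]; b2 <- lbl[-H, -1]     # SW-NE diagonal pairs
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, H, W)
  nz <- lbl > 0L
  out[nz] <- relab[lbl[nz]]
  out
}

#' Threshold a frame and label candidate regions
#'
#' Marks all pixels strictly darker than `grey_limit` as candidate-cell
#' foreground and labels connected components with 8-connectivity.
#' Components touching the frame border are retained.
#'
#' @param frame Numeric grey matrix.
#' @param grey_limit Grey-level limit from [determine_grey_limit()].
#' @return An integer label matrix (0 = background, 1..K = components).
#' @export
threshold_and_label <- function(frame, grey_limit) {
  label_components(frame < grey_limit)
}

# ---- boundary tracing and concavity cutting ------------------------------

# Moore-neighbour boundary trace of the region `id` in label matrix `lbl`.
# Returns an L x 2 matrix of (row, col), clockwise in screen coordinates.
trace_boundary <- function(lbl, id) {
  idx <- which(lbl == id, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]  # topmost, then leftmost
  H <- nrow(lbl); W <- ncol(lbl)
  inreg <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && lbl[r, c] == id
  # clockwise Moore neighbourhood in screen coords (x right, y down): E SE S SW W NW N NE
  nb <- matrix(c(0L,1L, 1L,1L, 1L,0L, 1L,-1L, 0L,-1L, -1L,-1L, -1L,0L, -1L,1L),
               ncol = 2, byrow = TRUE)  # (dr, dc)
  # backtrack starts to the West of the start pixel (guaranteed background)
  p <- start; back_dir <- 5L  # index of the neighbour we came from (W)
  path <- matrix(0L, 4L * (H + W) + 8L * nrow(idx), 2L)
  len <- 0L
  first_move <- NA_integer_
  repeat {
    len <- len + 1L
    if (len > nrow(path)) path <- rbind(path, path)  # safety growth
    path[len, ] <- p
    moved <- FALSE
    # scan clockwise starting just after the backtrack direction
    for (s in seq_len(8L)) {
      d <- ((back_dir - 1L + s) %% 8L) + 1L
      r <- p[1] + nb[d, 1]; c <- p[2] + nb[d, 2]
      if (inreg(r, c)) {
        # new backtrack: direction pointing from new pixel to the previously
        # scanned (background) neighbour of p
        prev_d <- ((d - 2L) %% 8L) + 1L
        br <- p[1] + nb[prev_d, 1] - r; bc <- p[2] + nb[prev_d, 2] - c
        back_dir <- which(nb[, 1] == clamp(br, -1L, 1L) & nb[, 2] == clamp(bc, -1L, 1L))[1]
        if (is.na(back_dir)) back_dir <- ((d + 3L) %% 8L) + 1L
        p <- c(r, c)
        if (is.na(first_move)) first_move <- d
        moved <- TRUE
        break
      }
    }
    if (!moved) break  # isolated pixel
    if (all(p == start) && len > 1L) break
    if (len > 8L * nrow(idx) + 8L) break  # guard
  }
  path[seq_len(len), , drop = FALSE]
}

# signed turning angle (degrees) at each boundary point over a +/- m window;
# normalised so convex points are positive regardless of trace direction
boundary_turning <- function(path, m) {
  L <- nrow(path)
  if (L < 2L * m + 1L) return(rep(0, L))
  im <- ((seq_len(L) - 1L - m) %% L) + 1L
  ip <- ((seq_len(L) - 1L + m) %% L) + 1L
  v1r <- path[, 1] - path[im, 1]; v1c <- path[, 2] - path[im, 2]
  v2r <- path[ip, 1] - path[, 1]; v2c <- path[ip, 2] - path[, 2]
  cross <- v1c * v2r - v1r * v2c   # z of (x1,y1) x (x2,y2) with x = col, y = row
  dot <- v1c * v2c + v1r * v2r
  turn <- atan2(cross, dot) * 180 / pi
  if (sum(turn) < 0) turn <- -turn
  turn
}

#' Cut touching cell regions at concave boundary points
#'
#' Regions larger than one `cutting_cell_diameter` disc are examined along
#' their traced boundary; points of strong concave turning ("necks") are
#' paired when the straight line between them is shorter than
#' `cutting_cell_diameter` and much shorter than the boundary path between
#' them (ratio > `path_ratio`, so a single bulge is never cut). The straight
#' line between each accepted pair is set to background and the mask is
#' relabelled; up to `max_passes` passes split triplets and larger clusters.
#'
#' @param lbl Integer label matrix from [threshold_and_label()].
#' @param cutting_cell_diameter Largest region diameter that is never cut,
#'   micrometres.
#' @param pixel_size Micrometres per pixel.
#' @param angle_threshold Minimal concave turning angle, degrees.
#' @param window Half-window (boundary steps) for the turning angle;
#'   default `max(3, round(0.25 * cutting_cell_diameter / pixel_size))`.
#' @param path_ratio Required boundary-path / straight-line ratio.
#' @param max_passes Maximum cutting passes.
#' @return A relabelled integer label matrix.
#' @export
cut_touching_regions <- function(lbl, cutting_cell_diameter, pixel_size,
                                 angle_threshold = 35, window = NULL,
                                 path_ratio = 2, max_passes = 3L) {
  d_px <- cutting_cell_diameter / pixel_size
  m <- window %||% max(3L, as.integer(round(0.25 * d_px)))
  disc_area <- pi * (d_px / 2)^2
  mask <- lbl > 0L
  for (pass in seq_len(max_passes)) {
    lbl <- label_components(mask)
    areas <- tabulate(lbl[lbl > 0L])
    big <- which(areas > disc_area)
    any_cut <- FALSE
    for (id in big) {
      path <- trace_boundary(lbl, id)
      L <- nrow(path)
      if (L < 2L * m + 1L) next
      turn <- boundary_turning(path, m)
      # neck points: concave local minima below -angle_threshold
      concave <- which(turn < -angle_threshold)
      if (length(concave) < 2L) next
      is_min <- vapply(concave, function(i) {
        win <- ((i - 1L + seq.int(-m, m)) %% L) + 1L
        turn[i] <= min(turn[win])
      }, TRUE)
      necks <- concave[is_min]
      if (length(necks) < 2L) next
      # thin runs of equal minima to one representative
      necks <- necks[c(TRUE, diff(necks) > m / 2)]
      if (length(necks) < 2L) next
      # cumulative arc length for boundary-path separation
      step <- sqrt(rowSums((path - path[c(2:L, 1L), ])^2))
      arc <- c(0, cumsum(step))[seq_len(L)]
      total <- arc[L] + step[L]
      cand <- list()
      for (a in seq_len(length(necks) - 1L)) {
        for (b in seq.int(a + 1L, length(necks))) {
          i <- necks[a]; j <- necks[b]
          ds <- sqrt(sum((path[i, ] - path[j, ])^2))
          if (ds >= d_px || ds < 1) next
          dp <- abs(arc[i] - arc[j]); dp <- min(dp, total - dp)
          if (dp <= path_ratio * ds) next
          cand[[length(cand) + 1L]] <- c(i, j, ds)
        }
      }
      if (!length(cand)) next
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, 3]), , drop = FALSE]
      used <- integer(0)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (i %in% used || j %in% used) next
        line <- bresenham(path[i, 1], path[i, 2], path[j, 1], path[j, 2])
        mask[line] <- FALSE
        used <- c(used, i, j)
        any_cut <- TRUE
      }
    }
    if (!any_cut) break
  }
  label_components(mask)
}

# ---- region measurement and size gating ----------------------------------

# region property table from a label matrix; centroids in micrometres of the
# uncropped frame (pixel centres; offset_px = (x, y) of the crop origin)
region_properties <- function(lbl, pixel_size, offset_px = c(x = 0, y = 0)) {
  n <- max(lbl)
  if (n == 0L) {
    return(tibble(label = integer(), area_px = integer(),
                  x = numeric(), y = numeric(), equivalent_diameter = numeric(),
                  xmin = integer(), xmax = integer(), ymin = integer(), ymax = integer()))
  }
  nz <- which(lbl > 0L)
  lab <- lbl[nz]
  rr <- ((nz - 1L) %% nrow(lbl)) + 1L
  cc <- ((nz - 1L) %/% nrow(lbl)) + 1L
  area <- tabulate(lab, nbins = n)
  sum_r <- unname(vapply(split(rr, lab), sum, 0))
  sum_c <- unname(vapply(split(cc, lab), sum, 0))
  x_px <- sum_c / area - 1 + offset_px[["x"]]
  y_px <- sum_r / area - 1 + offset_px[["y"]]
  area_um2 <- area * pixel_size^2
  tibble(
    label = seq_len(n),
    area_px = as.integer(area),
    x = x_px * pixel_size,
    y = y_px * pixel_size,
    equivalent_diameter = 2 * sqrt(area_um2 / pi),
    xmin = as.integer(unname(vapply(split(cc, lab), min, 0)) - 1L + offset_px[["x"]]),
    xmax = as.integer(unname(vapply(split(cc, lab), max, 0)) - 1L + offset_px[["x"]]),
    ymin = as.integer(unname(vapply(split(rr, lab), min, 0)) - 1L + offset_px[["y"]]),
    ymax = as.integer(unname(vapply(split(rr, lab), max, 0)) - 1L + offset_px[["y"]])
  )
}

#' Gate candidate regions by equivalent diameter
#'
#' Accepts candidates whose equivalent circular diameter (the diameter of
#' the circle with the same area as the region) lies within
#' `[smallest_cell_diameter, largest_cell_diameter]`; others are scrapped
#' and counted by cause.
#'
#' @param regions Region tibble from segmentation (columns include
#'   `equivalent_diameter`).
#' @param smallest_cell_diameter,largest_cell_diameter Size gates,
#'   micrometres.
#' @param grey_limit Grey limit used (carried into the result).
#' @return A `pt_segmentation` object: list with `grey_limit`, `regions`
#'   (all candidates with a `status` column: identified / too_small /
#'   too_large), and counts `n_candidates`, `n_identified`, `n_too_small`,
#'   `n_too_large`.
#' @export
identify_cells <- function(regions, smallest_cell_diameter, largest_cell_diameter,
                           grey_limit = NA_real_) {
  d <- regions$equivalent_diameter
  status <- dplyr::case_when(
    d < smallest_cell_diameter ~ "too_small",
    d > largest_cell_diameter ~ "too_large",
    .default = "identified"
  )
  regions$status <- status
  structure(list(
    grey_limit = grey_limit,
    regions = regions,
    n_candidates = nrow(regions),
    n_identified = sum(status == "identified"),
    n_too_small = sum(status == "too_small"),
    n_too_large = sum(status == "too_large")
  ), class = "pt_segmentation")
}

#' @export
print.pt_segmentation <- function(x, ...) {
  cat(sprintf("<phasetrack segmentation: %d candidates, %d identified (%d too small, %d too large), grey limit %.2f>\n",
              x$n_candidates, x$n_identified, x$n_too_small, x$n_too_large, x$grey_limit))
  invisible(x)
}

#' Segment one frame
#'
#' Full per-frame segmentation chain: contrast/flat-field preprocessing per
#' settings, Gaussian smoothing, grey-limit determination, crop to the
#' analysis region, thresholding with 8-connected labelling, concavity
#' cutting, region measurement (centroids in uncropped-frame micrometres)
#' and size gating.
#'
#' @param frame Numeric grey matrix (aligned if alignment is used).
#' @param settings A [settings()] object.
#' @param keep_labels Keep the cropped label matrix (for overlays) as
#'   attribute `"labels"`.
#' @return A `pt_segmentation` object.
#' @export
segment_frame <- function(frame, settings = default_settings(), keep_labels = FALSE) {
  frame <- preprocess_frame(frame, settings)
  sm <- gaussian_smooth(frame, settings$gaussian_radius, settings$pixel_size)
  cropped <- crop_frame(sm, settings$crop_top, settings$crop_bottom,
                        settings$crop_left, settings$crop_right)
  limit <- determine_grey_limit(cropped, settings$segmentation_limit)
  lbl <- threshold_and_label(cropped, limit)
  lbl <- cut_touching_regions(lbl, settings$cutting_cell_diameter, settings$pixel_size)
  props <- region_properties(lbl, settings$pixel_size, attr(cropped, "offset_px"))
  res <- identify_cells(props, settings$smallest_cell_diameter,
                        settings$largest_cell_diameter, grey_limit = limit)
  if (keep_labels) {
    attr(res, "labels") <- lbl
    attr(res, "offset_px") <- attr(cropped, "offset_px")
  }
  res
}
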