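# Frame preprocessing: contrast reversal, pseudo flat-field correction,
# Gaussian smoothing, cropping to the analysis region.

#' Reverse image contrast
#'
#' Maps grey level g to 255 - g. Needed for fluorescence-like series where
#' cells are brighter than the background: segmentation assumes dark nuclei
#' on a bright background.
#'
#' @param frame Numeric grey matrix in `[0, 255]`.
#' @return The contrast-reversed frame.
#' @export
reverse_contrast <- function(frame) 255 - frame

#' Gaussian smoothing
#'
#' Isotropic Gaussian filter with standard deviation
#' `sigma = gaussian_radius / pixel_size` pixels, reflective boundary.
#' Smearing out the dark intra-nuclear speckle before thresholding is what
#' makes a single grey-level limit segment whole nuclei; the filter radius
#' is therefore specified in micrometres, like the structures it removes.
#'
#' @param frame Numeric grey matrix.
#' @param gaussian_radius Kernel standard deviation, micrometres.
#' @param pixel_size Micrometres per pixel.
#' @return The smoothed frame.
#' @export
gaussian_smooth <- function(frame, gaussian_radius, pixel_size) {
  stopifnot(gaussian_radius > 0, pixel_size > 0)
  sigma <- gaussian_radius / pixel_size
  # truncate at 3 sigma, capped so reflection padding stays defined on
  # frames smaller than the nominal kernel (wide flat-field radii)
  k <- max(1L, min(ceiling(3 * sigma), nrow(frame) - 1L, ncol(frame) - 1L))
  g <- exp(-0.5 * (seq.int(-k, k) / sigma)^2)
  g <- g / sum(g)
  smooth_axis <- function(m) {
    n <- nrow(m)
    pad_top <- m[seq.int(k, 1L), , drop = FALSE]          # reflect
    pad_bot <- m[seq.int(n, n - k + 1L), , drop = FALSE]
    padded <- rbind(pad_top, m, pad_bot)
    out <- stats::filter(padded, g, sides = 2)
    matrix(out[seq.int(k + 1L, k + n), ], n, ncol(m))
  }
  t(smooth_axis(t(smooth_axis(frame))))
}

#' Pseudo flat-field correction
#'
#' Removes smooth, static background intensity structure (uneven
#' illumination, plate-etching artefacts such as the repositioning cross)
#' that would otherwise be segmented as spurious cells. The large-scale
#' background is estimated per frame as a wide Gaussian blur
#' (`background_radius`, much larger than any cell); the frame is levelled
#' as `frame - background + mean(background)` and clipped to `[0, 255]`.
#'
#' @param frame Numeric grey matrix.
#' @param background_radius Background blur radius, micrometres. Must exceed
#'   `largest_cell_diameter` so real cells are not flattened.
#' @param pixel_size Micrometres per pixel.
#' @param largest_cell_diameter Largest accepted cell diameter, micrometres
#'   (used only to validate `background_radius`).
#' @return The corrected frame.
#' @export
flat_field_correct <- function(frame, background_radius, pixel_size,
                               largest_cell_diameter = NULL) {
  if (!is.null(largest_cell_diameter) && background_radius <= largest_cell_diameter)
    stopf("Invalid setting 'Flat field radius': %g um must exceed the largest cell diameter (%g um)",
          background_radius, largest_cell_diameter)
  bg <- gaussian_smooth(frame, background_radius, pixel_size)
  clamp(frame - bg + mean(bg), 0, 255)
}

#' Crop a frame to the analysis region
#'
#' Returns the region `[crop_left, W - crop_right) x [crop_top, H - crop_bottom)`
#' with the pixel offset of its top-left corner recorded in the
#' `"offset_px"` attribute `(x, y)`, so downstream centroids can be reported
#' in the uncropped frame's coordinates.
#'
#' @param frame Numeric grey matrix.
#' @param crop_top,crop_bottom,crop_left,crop_right Margins in pixels.
#' @return The cropped frame with attribute `offset_px = c(x, y)` in pixels.
#' @export
crop_frame <- function(frame, crop_top = 0L, crop_bottom = 0L,
                       crop_left = 0L, crop_right = 0L) {
  H <- nrow(frame); W <- ncol(frame)
  rows <- seq.int(crop_top + 1L, H - crop_bottom)
  cols <- seq.int(crop_left + 1L, W - crop_right)
  if (crop_top + crop_bottom >= H || crop_left + crop_right >= W)
    stopf("Crop margins leave an empty region (%d x %d frame)", H, W)
  out <- frame[rows, cols, drop = FALSE]
  attr(out, "offset_px") <- c(x = as.integer(crop_left), y = as.integer(crop_top))
  out
}

#' Flat-field correct a whole stack using its static background
#'
#' Static artefacts (the plate-etching cross, uneven illumination) persist
#' across frames while cells move, so the per-pixel temporal median of the
#' series isolates the static background far better than any single-frame
#' spatial estimate can when artefacts are only a few cell diameters wide.
#' The median frame, lightly blurred (2 um) to suppress residual noise, is
#' subtracted from every frame and the global background mean restored.
#'
#' @param stack A `pt_stack`.
#' @param settings A [settings()] object (`pixel_size` used for the blur).
#' @return The corrected `pt_stack`.
#' @export
flat_field_stack <- function(stack, settings = default_settings()) {
  H <- nrow(stack$frames[[1]]); W <- ncol(stack$frames[[1]])
  n <- length(stack$frames)
  take <- if (n > 25L) round(seq(1, n, length.out = 25L)) else seq_len(n)
  arr <- array(unlist(stack$frames[take]), dim = c(H, W, length(take)))
  bg <- apply(arr, c(1, 2), median)
  bg <- gaussian_smooth(bg, 2, settings$pixel_size)
  mu <- mean(bg)
  frames <- lapply(stack$frames, function(f) clamp(f - bg + mu, 0, 255))
  image_stack(frames, stack$pixel_size, stack$dt)
}

# apply the per-frame preprocessing chain dictated by settings (contrast
# reversal and flat-field; smoothing/cropping happen inside segmentation).
# Stack-level static-background correction (flat_field_stack) is applied by
# the pipeline instead when a whole series is available.
preprocess_frame <- function(frame, settings) {
  if (settings$contrast_reversal) frame <- reverse_contrast(frame)
  if (settings$flat_field_correction) {
    frame <- flat_field_correct(frame, settings$flat_field_radius,
                                settings$pixel_size, settings$largest_cell_diameter)
  }
  frame
}
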