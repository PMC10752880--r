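# ImageStack container and lossless TIFF input/output.
#
# Frames are plain numeric matrices holding grey levels in [0, 255]
# (floating point during processing). Matrix element [r, c] is the pixel at
# x = (c - 1), y = (r - 1) in pixel units, x rightward and y downward;
# physical positions are pixel index * pixel_size, in micrometres.

#' Construct an image stack
#'
#' @param frames List of numeric matrices with identical dimensions, grey
#'   levels in `[0, 255]`.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @param dt Time between retained frames, minutes.
#' @return A `pt_stack` object.
#' @export
image_stack <- function(frames, pixel_size, dt) {
  if (length(frames) < 2L) stopf("An image stack needs at least 2 frames, got %d", length(frames))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("All frames must share the same dimensions")
  if (!all(vapply(frames, function(f) all(is.finite(f)), TRUE)))
    stopf("Frames must contain finite grey levels")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  if (dt <= 0) stopf("dt must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size, dt = dt),
            class = "pt_stack")
}

#' @export
print.pt_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<phasetrack image stack: %d frames of %d x %d px, %.4g um/px, dt = %.4g min>\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$dt))
  invisible(x)
}

#' @export
length.pt_stack <- function(x) length(x$frames)

.to_grey_matrix <- function(a) {
  # tiff/png readers return [0,1] arrays; colour as H x W x C
  if (length(dim(a)) == 3L) {
    ch <- dim(a)[3]
    if (ch >= 3L) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  a * 255
}

#' Read an image series into a stack
#'
#' Reads a multi-page (or single-page-per-file directory of) TIFF image
#' series. Colour frames are converted to luminance; grey levels are scaled
#' to `[0, 255]` and frame order is preserved. When
#' `settings$skip_images = n > 0`, every (n+1)-th frame is retained and the
#' frame interval is scaled by (n+1), mimicking a series imaged less often.
#'
#' @param path Path to a multi-page TIFF file, or a directory of `.tif`/
#'   `.tiff`/`.png` frames read in lexicographic order.
#' @param settings A [settings()] object supplying `pixel_size`,
#'   `time_between_images` and `skip_images`.
#' @return A [image_stack()] object.
#' @export
read_stack <- function(path, settings = default_settings()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tiff?|png)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stopf("No TIFF/PNG frames found in directory '%s'", path)
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
          stopf("Reading PNG frames requires the 'png' package")
        .to_grey_matrix(png::readPNG(f))
      } else {
        .to_grey_matrix(tiff::readTIFF(f))
      }
    })
  } else {
    if (!file.exists(path)) stopf("Cannot read image series '%s'", path)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stopf("Cannot decode '%s': %s", path, conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, .to_grey_matrix)
  }
  n_skip <- settings$skip_images
  keep <- seq(1L, length(frames), by = n_skip + 1L)
  frames <- frames[keep]
  if (length(frames) < 2L)
    stopf("Fewer than 2 frames retained from '%s' (skip_images = %d)", path, n_skip)
  image_stack(frames, pixel_size = settings$pixel_size,
              dt = settings$time_between_images * (n_skip + 1L))
}

#' Write a stack as a multi-page TIFF
#'
#' Grey levels are stored as 8-bit unless `bits = 16`; the TIFF path is
#' lossless, so `read_stack(write_stack(x))` reproduces grey levels exactly
#' (after integer quantisation of non-integer working values).
#'
#' @param stack A `pt_stack`.
#' @param path Output `.tif` path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 8L) {
  imgs <- lapply(stack$frames, function(f) clamp(round(f), 0, 255) / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}
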