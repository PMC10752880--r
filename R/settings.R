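# Settings: parsing, validation, defaults, round-trip persistence.
#
# The settings file is plain text, one "Key = value" per line, with the key
# vocabulary of the original tool's defaults file ("Pixel size",
# "Gaussian filter radius", "Segmentation limit", ...). Keys are matched
# case-insensitively and tolerant of punctuation; both the ASCII minus and
# the typographic en-dash / minus sign are accepted in numbers.

# canonical field -> file key and type ("num", "int", "flag", "seglim")
.settings_schema <- list(
  pixel_size            = list(key = "Pixel size",                 type = "num",  default = 0.645),
  time_between_images   = list(key = "Time between images",        type = "num",  default = 10),
  gaussian_radius       = list(key = "Gaussian filter radius",     type = "num",  default = 10),
  smallest_cell_diameter = list(key = "Smallest cell diameter",    type = "num",  default = 6),
  largest_cell_diameter = list(key = "Largest cell diameter",      type = "num",  default = 30),
  cutting_cell_diameter = list(key = "Cutting cell diameter",      type = "num",  default = 20),
  highest_cell_velocity = list(key = "Highest cell velocity",      type = "num",  default = 10),
  shortest_cell_track   = list(key = "Shortest cell track",        type = "int",  default = 5),
  crop_top              = list(key = "Top crop margin",            type = "int",  default = 0),
  crop_bottom           = list(key = "Bottom crop margin",         type = "int",  default = 0),
  crop_left             = list(key = "Left crop margin",           type = "int",  default = 0),
  crop_right            = list(key = "Right crop margin",          type = "int",  default = 0),
  segmentation_limit    = list(key = "Segmentation limit",         type = "seglim", default = "auto"),
  shift_correction      = list(key = "Image shift correction",     type = "flag", default = TRUE),
  flat_field_correction = list(key = "Flat field correction",      type = "flag", default = FALSE),
  flat_field_radius     = list(key = "Flat field radius",          type = "num",  default = 100),
  contrast_reversal     = list(key = "Contrast reversal",          type = "flag", default = FALSE),
  wound_healing_mode    = list(key = "Wound healing mode",         type = "flag", default = FALSE),
  skip_images           = list(key = "Skip images",                type = "int",  default = 0),
  smoothing_iterations  = list(key = "Track smoothing iterations", type = "int",  default = 0),
  max_shift_search      = list(key = "Maximum shift search",       type = "int",  default = 20),
  random_seed           = list(key = "Random seed",                type = "int",  default = 1)
)

.norm_key <- function(k) gsub("[^a-z0-9]", "", tolower(k))

# file-key lookup: normalised key -> field name (plus a few aliases)
.settings_key_map <- local({
  m <- setNames(names(.settings_schema),
                vapply(.settings_schema, function(s) .norm_key(s$key), ""))
  m[.norm_key("Perform flat-field correction")] <- "flat_field_correction"
  m[.norm_key("Segmentation Limit")] <- "segmentation_limit"
  m
})

.parse_number <- function(value, line = NA_integer_) {
  # normalise typographic minus signs (the defaults listing prints "=- 1.5")
  v <- gsub("–|—|−", "-", value)
  v <- gsub("\\s+", "", v)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) {
    stopf("Cannot parse numeric value '%s'%s", value,
          if (is.na(line)) "" else sprintf(" (line %d)", line))
  }
  x
}

.parse_flag <- function(value, line = NA_integer_) {
  v <- tolower(trimws(value))
  if (v %in% c("yes", "true", "on", "1")) return(TRUE)
  if (v %in% c("no", "false", "off", "0")) return(FALSE)
  stopf("Cannot parse yes/no value '%s'%s", value,
        if (is.na(line)) "" else sprintf(" (line %d)", line))
}

#' Default analysis settings
#'
#' Returns the full default [settings()] object. Numeric defaults suit
#' Incucyte S3 phase-contrast series (0.645 um pixels,
#' 10 um Gaussian filter radius, 6-30 um cell diameters, 10 um/min highest
#' cell velocity, 5-frame shortest track); the segmentation limit defaults to
#' `"auto"` (background-peak rule).
#'
#' @return A `pt_settings` object (named list).
#' @export
#' @examples
#' default_settings()$pixel_size
default_settings <- function() {
  out <- lapply(.settings_schema, `[[`, "default")
  structure(out, class = "pt_settings")
}

#' Create or modify analysis settings
#'
#' @param ... Named settings fields overriding the defaults, e.g.
#'   `settings(pixel_size = 1, segmentation_limit = -1.5)`.
#' @param .base Settings object to start from (default [default_settings()]).
#' @return A validated `pt_settings` object.
#' @export
settings <- function(..., .base = default_settings()) {
  upd <- list(...)
  bad <- setdiff(names(upd), names(.settings_schema))
  if (length(bad)) stopf("Unknown settings field(s): %s", paste(bad, collapse = ", "))
  out <- unclass(.base)
  out[names(upd)] <- upd
  validate_settings(structure(out, class = "pt_settings"))
}

#' Validate settings invariants
#'
#' Checks positivity of physical scales, ordering of the cell-diameter gates
#' (smallest <= cutting <= largest), and non-negative crop margins. Errors name
#' the offending key.
#'
#' @param s A `pt_settings` object.
#' @return `s`, invisibly validated (returned unchanged on success).
#' @export
validate_settings <- function(s) {
  chk <- function(ok, key, msg) if (!ok) stopf("Invalid setting '%s': %s", key, msg)
  chk(s$pixel_size > 0, "Pixel size", "must be > 0")
  chk(s$time_between_images > 0, "Time between images", "must be > 0")
  chk(s$gaussian_radius > 0, "Gaussian filter radius", "must be > 0")
  chk(s$smallest_cell_diameter > 0, "Smallest cell diameter", "must be > 0")
  chk(s$smallest_cell_diameter < s$largest_cell_diameter,
      "Largest cell diameter", "must exceed the smallest cell diameter")
  chk(s$cutting_cell_diameter >= s$smallest_cell_diameter &&
      s$cutting_cell_diameter <= s$largest_cell_diameter,
      "Cutting cell diameter", "must lie between the smallest and largest cell diameters")
  chk(s$highest_cell_velocity > 0, "Highest cell velocity", "must be > 0")
  chk(s$shortest_cell_track >= 2, "Shortest cell track", "must be at least 2 frames")
  for (k in c("crop_top", "crop_bottom", "crop_left", "crop_right"))
    chk(s[[k]] >= 0, .settings_schema[[k]]$key, "must be >= 0")
  chk(s$skip_images >= 0, "Skip images", "must be >= 0")
  chk(s$smoothing_iterations >= 0, "Track smoothing iterations", "must be >= 0")
  if (!identical(s$segmentation_limit, "auto")) {
    chk(is.numeric(s$segmentation_limit) && s$segmentation_limit < 0,
        "Segmentation limit", "must be 'auto' or a negative number")
  }
  chk(s$flat_field_radius > s$largest_cell_diameter,
      "Flat field radius", "must exceed the largest cell diameter")
  s
}

#' Parse a settings file
#'
#' Reads plain-text `Key = value` settings. Keys are case-insensitive and
#' matched ignoring punctuation; unknown keys produce a warning and are
#' ignored; absent keys take their documented defaults. Both `-1.5` and the
#' typographically printed `– 1.5` parse as negative numbers.
#'
#' @param path Path to a settings file, or a character vector of
#'   `Key = value` lines (anything containing `=` or of length > 1 is treated
#'   as literal content).
#' @return A validated `pt_settings` object.
#' @export
#' @examples
#' s <- load_settings(c("Pixel size = 0.645", "Segmentation limit = -1.5"))
#' s$segmentation_limit
load_settings <- function(path) {
  literal <- length(path) != 1L || path == "" ||
    grepl("=", path, fixed = TRUE) || grepl("\n", path, fixed = TRUE)
  lines <- if (literal) unlist(strsplit(path, "\n", fixed = TRUE)) else readLines(path, warn = FALSE)
  out <- unclass(default_settings())
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    value <- trimws(sub("^[^=]*=", "", ln))
    field <- unname(.settings_key_map[.norm_key(key)])
    if (is.na(field)) {
      warnf("Ignoring unknown settings key '%s' (line %d)", key, i)
      next
    }
    type <- .settings_schema[[field]]$type
    out[[field]] <- switch(type,
      num  = .parse_number(value, i),
      int  = as.integer(round(.parse_number(value, i))),
      flag = .parse_flag(value, i),
      seglim = if (tolower(gsub("\\s", "", value)) == "auto") "auto" else .parse_number(value, i)
    )
  }
  validate_settings(structure(out, class = "pt_settings"))
}

#' Write settings to a file
#'
#' Writes the canonical `Key = value` representation, suitable for re-reading
#' with [load_settings()] (save/load round-trips identically). Used by the
#' batch runner to store the settings actually used with each result set.
#'
#' @param s A `pt_settings` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_settings <- function(s, path) {
  fmt <- function(field) {
    v <- s[[field]]
    if (is.logical(v)) v <- if (v) "yes" else "no"
    sprintf("%s = %s", .settings_schema[[field]]$key, format(v, scientific = FALSE))
  }
  writeLines(vapply(names(.settings_schema), fmt, ""), path)
  invisible(path)
}

#' @export
print.pt_settings <- function(x, ...) {
  cat("<phasetrack settings>\n")
  for (field in names(.settings_schema)) {
    v <- x[[field]]
    if (is.logical(v)) v <- if (v) "yes" else "no"
    cat(sprintf("  %-26s %s\n", .settings_schema[[field]]$key, format(v)))
  }
  invisible(x)
}
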