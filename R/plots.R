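# ggplot2 figures mirroring the standard output suite: size distribution,
# velocity histogram with fitted parabola, velocity vs time, trajectory
# plots (common origin and in place), Bland-Altman agreement.

#' Size-distribution plot
#'
#' Equivalent-diameter distributions of all candidate regions (grey) and
#' of the identified cells (green); the visual check that the size gates
#' are reasonable.
#'
#' @param segmentations List of `pt_segmentation`.
#' @param binwidth Histogram bin width, micrometres.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(segmentations, binwidth = 1) {
  regions <- dplyr::bind_rows(lapply(segmentations, function(s) s$regions))
  idf <- dplyr::filter(regions, .data$status == "identified")
  ggplot2::ggplot(regions, ggplot2::aes(x = .data$equivalent_diameter)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey60", colour = NA) +
    ggplot2::geom_histogram(data = idf, binwidth = binwidth,
                            fill = "forestgreen", alpha = 0.8, colour = NA) +
    ggplot2::labs(x = "Equivalent circular diameter (µm)", y = "Regions",
                  title = "Candidate (grey) and identified (green) cell sizes") +
    ggplot2::theme_minimal()
}

#' @method autoplot pt_distribution
#' @export
autoplot.pt_distribution <- function(object, ...) {
  b <- object$bins
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pct), fill = "firebrick", alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_pct / max(.data$cum_pct) * max(.data$pct)),
                       linetype = "dashed", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mode, colour = "steelblue") +
    ggplot2::labs(x = "Value", y = "% of steps",
                  subtitle = sprintf("mode %.3g, median %.3g, mean %.3g",
                                     object$mode, object$median, object$mean)) +
    ggplot2::theme_minimal()
  # the fitted parabola around the peak
  peak <- which.max(b$count)
  if (peak > 2 && peak + 2 <= nrow(b)) {
    w <- (peak - 2):(peak + 2)
    fit <- stats::lm(pct ~ poly(bin_mid, 2, raw = TRUE), data = b[w, ])
    xs <- seq(b$bin_mid[peak - 2], b$bin_mid[peak + 2], length.out = 50)
    pred <- tibble(bin_mid = xs, pct = stats::predict(fit, tibble(bin_mid = xs)))
    p <- p + ggplot2::geom_line(data = pred, ggplot2::aes(y = .data$pct),
                                colour = "steelblue", linewidth = 1)
  }
  p
}

#' Velocity-versus-time plot
#'
#' @param frame_summary Tibble from [mean_velocity_over_time()].
#' @return A ggplot; dots are per-step mean velocities, the line the
#'   overall mean, the lower trace the velocity-sum-per-cell diagnostic.
#' @export
plot_velocity_time <- function(frame_summary) {
  ggplot2::ggplot(frame_summary, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_velocity), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = mean(frame_summary$mean_velocity, na.rm = TRUE)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$velocity_sum_per_cell),
                       colour = "grey50", na.rm = TRUE) +
    ggplot2::labs(x = "Time (min)", y = "Mean velocity (µm/min)") +
    ggplot2::theme_minimal()
}

#' Trajectory plot
#'
#' @param object A `pt_tracks` tibble.
#' @param origin `"common"` translates every track to start at (0, 0);
#'   `"in_place"` keeps image positions (y axis inverted for display).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pt_tracks
#' @export
autoplot.pt_tracks <- function(object, origin = c("in_place", "common"), ...) {
  origin <- match.arg(origin)
  d <- if (origin == "common") common_origin(object) else object
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$track,
                                       colour = factor(.data$track))) +
    ggplot2::geom_path(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if (origin == "in_place") p <- p + ggplot2::scale_y_reverse()
  p
}

#' @method autoplot pt_agreement
#' @export
autoplot.pt_agreement <- function(object, ...) {
  ggplot2::ggplot(object$differences,
                  ggplot2::aes(x = .data$mean_velocity, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper), linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (µm/min)",
                  y = "Difference (µm/min)",
                  title = "Bland–Altman velocity agreement") +
    ggplot2::theme_minimal()
}

#' Write the standard PNG plot suite for a run
#'
#' @param run A `pt_run`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the files written.
#' @export
write_plots <- function(run, dir, prefix = "phasetrack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  files <- character(0)
  save <- function(plot, name) {
    path <- p(name)
    ggplot2::ggsave(path, plot, width = 6, height = 4, dpi = 120)
    files <<- c(files, path)
  }
  save(plot_size_distribution(run$segmentations), "Size_distribution.png")
  if (!is.null(run$velocity_dist))
    save(autoplot(run$velocity_dist) +
           ggplot2::labs(x = "Step velocity (µm/min)"), "Velocity_histogram.png")
  if (!is.null(run$frame_summary))
    save(plot_velocity_time(run$frame_summary), "Velocity_vs_time.png")
  if (nrow(run$valid_tracks)) {
    save(autoplot(run$valid_tracks, origin = "in_place"), "Trajectories_in_place.png")
    save(autoplot(run$valid_tracks, origin = "common"), "Trajectories_common_origin.png")
  }
  invisible(files)
}
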