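#' Plot a gaze recording
#'
#' Horizontal and vertical gaze position against time, faceted by trial,
#' with tracking-loss samples omitted. Optionally shades detected saccades.
#'
#' @param object A [gaze_recording()].
#' @param trials Trial indices to show (default: first 4).
#' @param events Optional `gaze_events` tibble with a `trial` column;
#'   saccade spans are shaded.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gaze_recording <- function(object, trials = NULL, events = NULL,
                                    ...) {
  if (is.null(trials)) trials <- head(trial_indices(object), 4)
  s <- object$samples[object$samples$trial %in% trials &
                        object$samples$valid, ]
  long <- tidyr::pivot_longer(s, c("x", "y"), names_to = "axis",
                              values_to = "position")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$position,
                                          colour = .data$axis)) +
    ggplot2::facet_wrap(~trial, scales = "free_x") +
    ggplot2::labs(x = "time (ms)", y = "gaze position (deg)",
                  colour = NULL)
  if (!is.null(events)) {
    sac <- events[events$event == "saccade" & events$trial %in% trials, ]
    if (nrow(sac)) {
      p <- p + ggplot2::geom_rect(
        data = sac,
        ggplot2::aes(xmin = .data$onset, xmax = .data$offset),
        ymin = -Inf, ymax = Inf, fill = "grey80", alpha = 0.5,
        inherit.aes = FALSE)
    }
  }
  p + ggplot2::geom_line(linewidth = 0.3)
}

#' Plot detected events on the 2-D gaze plane
#'
#' Fixation centroids (points scaled by duration) and saccades (segments
#' from start to end position).
#'
#' @param object A `gaze_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gaze_events <- function(object, ...) {
  fix <- object[object$event == "fixation", ]
  sac <- object[object$event == "saccade", ]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = sac,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick") +
    ggplot2::geom_point(
      data = fix,
      ggplot2::aes(.data$cx, .data$cy, size = .data$duration),
      alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", size = "fixation (ms)")
}

#' Plot calibration accuracy
#'
#' Per-target mean error of a fitted calibration model: targets drawn at
#' their screen positions, coloured by mean prediction error.
#'
#' @param object A `gaze_calibration` fitted by [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gaze_calibration <- function(object, ...) {
  if (is.null(object$per_target)) {
    abort("model has no per-target fit report; fit it with fit_calibration()")
  }
  ggplot2::ggplot(object$per_target,
                  ggplot2::aes(.data$target_x, .data$target_y,
                               colour = .data$mean_error)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  colour = "mean error (deg)")
}
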