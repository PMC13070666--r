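#' Plot the movement signal with detected changes
#'
#' @param analysis A `cpm_analysis`.
#' @return A ggplot: combined derivative signal over time, detected change
#'   times as vertical lines.
#' @export
plot_movement_signal <- function(analysis) {
  ggplot2::ggplot(analysis$signal, ggplot2::aes(.data$t_s / 3600, .data$signal)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(xintercept = analysis$segmentation$change_times_s / 3600,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "time (h)", y = "combined derivative (robust z-norm)",
                  title = "Movement signal and detected postural changes")
}

#' Plot per-posture signatures against the sigmoid thresholds
#'
#' One marker per static posture at its (duration, mean magnitude) point,
#' with SD error bars, over the three boundary curves — the standard
#' pressure-time exposure chart.
#'
#' @param signatures Per-posture signatures ([posture_signatures()]).
#' @param thr A [sigmoid_thresholds()]; its `signature_type` selects which
#'   magnitude column is plotted.
#' @param t_max_h Right edge of the duration axis (default: a little past
#'   the longest posture).
#' @return A ggplot.
#' @export
plot_exposure <- function(signatures, thr = sigmoid_thresholds("ppi"),
                          t_max_h = NULL) {
  st <- thr$signature_type
  mcol <- paste0(st, "_mean")
  scol <- paste0(st, "_sd")
  t_max_h <- t_max_h %||% max(signatures$duration_h) * 1.2
  grid <- tidyr::expand_grid(t_h = seq(0.01, t_max_h, length.out = 200),
                             curve = factor(1:3))
  grid$boundary <- exposure_boundary(grid$t_h, as.integer(grid$curve), thr)
  unit <- if (st == "ppg") "mmHg/cm" else "mmHg"
  ggplot2::ggplot(signatures,
                  ggplot2::aes(.data$duration_h, .data[[mcol]])) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(.data$t_h, .data$boundary,
                                    group = .data$curve),
                       colour = "red") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "posture duration (h)",
                  y = sprintf("mean %s (%s)", toupper(st), unit),
                  title = sprintf("%s pressure-time exposure", toupper(st)))
}

#' @rdname plot_movement_signal
#' @param object,... `autoplot` method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.cpm_analysis <- function(object, ...) plot_movement_signal(object)
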