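#' Plot an epoch-level angle series with detected bouts
#'
#' The diagnostic view of the detector: the arm angle trace over time, with
#' detected sustained-inactivity bouts shaded and, optionally, the reported
#' sleep window marked.
#'
#' @param angles Angle series from [compute_angle_series()].
#' @param bouts Optional bout tibble ([detect_bouts()]).
#' @param onset,waking Optional reported sleep period to mark.
#' @return A ggplot object.
#' @export
plot_angle_series <- function(angles, bouts = NULL, onset = NULL, waking = NULL) {
  p <- ggplot2::ggplot(angles, ggplot2::aes(x = .data$epoch_start, y = .data$angle_deg))
  if (!is.null(bouts) && nrow(bouts)) {
    p <- p + ggplot2::geom_rect(
      data = bouts,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -90, ymax = 90, fill = "steelblue", alpha = 0.25,
      inherit.aes = FALSE
    )
  }
  if (!is.null(onset)) p <- p + ggplot2::geom_vline(xintercept = onset, linetype = 2)
  if (!is.null(waking)) p <- p + ggplot2::geom_vline(xintercept = waking, linetype = 2)
  p +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "arm angle (deg)") +
    ggplot2::ylim(-90, 90) +
    ggplot2::theme_minimal()
}

#' @describeIn cross_tabulate Tile plot of the confusion matrix with counts
#'   and per-column percentages.
#' @param object A `sleep_confusion` matrix.
#' @export
autoplot.sleep_confusion <- function(object, ...) {
  df <- tidy.sleep_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$survey, y = .data$accelerometer,
                                   fill = .data$col_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "% of column") +
    ggplot2::labs(x = "self-reported sleep duration (h)",
                  y = "accelerometer estimate (h)") +
    ggplot2::theme_minimal()
}

#' Plot a parameter-sweep grid
#'
#' Sensitivity, specificity, accuracy and bias against the minimum bout
#' duration, one line per angle threshold.
#'
#' @param grid Result of [parameter_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(grid) {
  long <- tidyr::pivot_longer(
    grid,
    c("accuracy_pct", "sensitivity_pct", "specificity_pct", "bias_min"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_min, y = .data$value,
                                     colour = factor(.data$angle_deg))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time window (min)", y = NULL,
                  colour = "angle (deg)") +
    ggplot2::theme_minimal()
}
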