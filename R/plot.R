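# ggplot2 views of the main result types.

#' Plot angle curves
#'
#' Joint angles over time or over the gait cycle, one panel per joint and
#' plane. Normalized input (a `cycle` column) shows per-stride traces and
#' the stride mean.
#'
#' @param curves Output of [afm_joint_angles()] or [normalize_gait_cycle()].
#' @return A ggplot object.
#' @export
plot_angle_curves <- function(curves) {
  if ("cycle" %in% names(curves)) {
    avg <- stride_average(curves)
    ggplot2::ggplot(curves, ggplot2::aes(x = .data$cycle, y = .data$angle)) +
      ggplot2::geom_line(
        ggplot2::aes(group = .data$stride),
        alpha = 0.35, linewidth = 0.3
      ) +
      ggplot2::geom_line(data = avg, colour = "black", linewidth = 0.8) +
      ggplot2::facet_grid(joint ~ plane, scales = "free_y") +
      ggplot2::labs(x = "gait cycle (%)", y = "angle (deg)")
  } else {
    ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$angle)) +
      ggplot2::geom_line(linewidth = 0.4, na.rm = TRUE) +
      ggplot2::facet_grid(joint ~ plane, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = "angle (deg)")
  }
}

#' Plot a marker-placement sensitivity table
#'
#' Gradient (deg/mm) per marker and displacement axis, faceted by segment
#' and anatomical plane.
#'
#' @param table An `afm_sensitivity` tibble.
#' @param threshold Optional reference line (e.g. 1 deg/mm).
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(table, threshold = 1) {
  p <- ggplot2::ggplot(
    table,
    ggplot2::aes(x = .data$marker, y = .data$gradient, fill = .data$axis)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(segment ~ plane, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "sensitivity (deg/mm)", fill = "displacement")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_sensitivity
#' @param object An `afm_sensitivity`.
#' @param ... Passed to [plot_sensitivity()].
#' @export
autoplot.afm_sensitivity <- function(object, ...) plot_sensitivity(object, ...)

#' @rdname repeatability
#' @param object An `afm_repeatability`.
#' @export
autoplot.afm_repeatability <- function(object, ...) {
  ggplot2::ggplot(
    object$sigma,
    ggplot2::aes(x = .data$joint, y = .data$sigma, fill = .data$comparison)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_grid(quantity ~ plane, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "sigma (deg)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
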