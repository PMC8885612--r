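#' Diagnostic plot of a detection result
#'
#' Overlays the raw acceleration, the 1 s absolute-mean envelope, the
#' soft-shrunk smoothed derivative (rescaled for visibility) and the
#' detected compression periods (shaded), mirroring the standard
#' workflow illustration of the method.
#'
#' @param object A `cc_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_detection
#' @export
autoplot.cc_detection <- function(object, ...) {
  env <- object$env
  d <- object$deriv
  d_scale <- max(abs(d$d), 1e-12)
  e_scale <- max(env$e, 1e-12)
  seg <- object$segmentation
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(
      data = object$trace,
      ggplot2::aes(x = .data$t, y = .data$v - mean(.data$v)),
      colour = "grey80", linewidth = 0.2
    ) +
    ggplot2::geom_line(
      data = env, ggplot2::aes(x = .data$t, y = .data$e),
      colour = "steelblue"
    ) +
    ggplot2::geom_line(
      data = d,
      ggplot2::aes(x = .data$t, y = .data$d / d_scale * e_scale),
      colour = "firebrick", linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::labs(
      x = "time since device power-on [s]",
      y = "acceleration [internal units]",
      title = "Chest-compression period detection",
      subtitle = "envelope (blue), shrunk derivative (red, rescaled), periods (green)"
    ) +
    ggplot2::theme_minimal()
  if (nrow(seg) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$stop_s,
                   ymin = -Inf, ymax = Inf),
      fill = "darkgreen", alpha = 0.12
    )
  }
  p
}

#' Plot matched-boundary deviations of an agreement report
#'
#' @param object A `cc_agreement`.
#' @param ... Unused.
#' @return A ggplot object: signed deviation (algorithm minus annotation)
#'   per matched boundary, with the matching tolerance shown as dashed
#'   lines.
#' @method autoplot cc_agreement
#' @export
autoplot.cc_agreement <- function(object, ...) {
  m <- object$matched
  ggplot2::ggplot(m, ggplot2::aes(x = .data$t_ann, y = .data$deviation_s,
                                  colour = .data$kind)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(
      yintercept = c(-1, 1) * object$tolerance_s,
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "annotated boundary time [s]",
      y = "deviation, algorithm - annotation [s]",
      colour = "marker"
    ) +
    ggplot2::theme_minimal()
}
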