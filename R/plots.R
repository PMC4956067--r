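# ggplot2 methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Bland-Altman agreement analysis
#'
#' Per-participant mean count against count difference, with the mean
#' difference (solid) and the 1.96-SD limits of agreement (dotted).
#'
#' @param object An `fms_ba` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fms_ba
#' @export
autoplot.fms_ba <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted") +
    ggplot2::labs(x = "Mean of the two counts",
                  y = "Difference between counts") +
    ggplot2::theme_minimal()
}

#' Plot joint trajectories of a skeleton stream
#'
#' One panel per requested joint, one line per axis, with detected matches
#' (optional) and exclusion intervals shaded.
#'
#' @param object A [skeleton_stream()].
#' @param joints Joints to show (default: the joints used by the built-in
#'   rules).
#' @param axes Axes to show (subset of `c("x", "y", "z")`).
#' @param matches Optional `fms_matches` table to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot skeleton_stream
#' @export
autoplot.skeleton_stream <- function(object,
                                     joints = c("head", "hip_centre",
                                                "ankle_left", "foot_right"),
                                     axes = c("x", "y"),
                                     matches = NULL, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  df <- df[df$joint %in% joints, c("time", "joint", "x", "y", "z")]
  long <- tidyr::pivot_longer(df, cols = c("x", "y", "z"),
                              names_to = "axis", values_to = "position")
  long <- long[long$axis %in% axes, ]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = time, y = position,
                                          colour = axis)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Position (m)", colour = "Axis") +
    ggplot2::theme_minimal()
  excl <- attr(object, "exclusions")
  if (!is.null(excl) && nrow(excl) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(excl),
      ggplot2::aes(xmin = start_s, xmax = end_s, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15
    )
  }
  if (!is.null(matches) && nrow(matches) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(matches),
      ggplot2::aes(xmin = start_s, xmax = end_s, ymin = -Inf, ymax = Inf,
                   fill = rule),
      inherit.aes = FALSE, alpha = 0.2
    ) + ggplot2::labs(fill = "Rule")
  }
  p
}

#' @rdname autoplot.fms_ba
#' @param x Object to plot (base-graphics entry point; delegates to
#'   `autoplot`).
#' @param y Unused.
#' @export
plot.fms_ba <- function(x, y, ...) print(autoplot.fms_ba(x, ...))
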