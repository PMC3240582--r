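#' @method autoplot meta_profile
#' @export
autoplot.meta_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$offset, y = .data$mean,
                               colour = factor(.data$group))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = paste("distance from", unique(object$anchor), "(bp)"),
                  y = "mean score (trimmed)", colour = "expression\ngroup") +
    ggplot2::theme_minimal()
}

#' @method autoplot position_histogram
#' @export
autoplot.position_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$offset, y = .data$value,
                               fill = .data$orientation)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "offset from anchor (bp)",
                  y = "normalized read number (ChIP - mock, per 1e7 tags)") +
    ggplot2::theme_minimal()
}

#' @method autoplot junction_profile
#' @export
autoplot.junction_profile <- function(object, ...) {
  autoplot.position_histogram(object) +
    ggplot2::facet_wrap(~ .data$type, ncol = 1)
}

#' FDR curve with the selected reporting threshold
#'
#' @param x An `fdr_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_fdr_curve <- function(x, ...) {
  stopifnot(inherits(x, "fdr_track"))
  p <- ggplot2::ggplot(x$curve, ggplot2::aes(x = .data$score, y = .data$fdr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = x$alpha, linetype = 2, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "adjusted score threshold", y = "empirical FDR") +
    ggplot2::theme_minimal()
  if (is.finite(x$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = x$threshold, linetype = 3)
  }
  p
}

#' Percentile feature-composition plot
#'
#' @param x A [percentile_composition()] result.
#' @param ... Unused.
#' @return A ggplot with genome-wide baselines as dashed lines.
#' @method autoplot percentile_composition
#' @export
autoplot.percentile_composition <- function(x, ...) {
  baseline <- attr(x, "baseline")
  bl <- tibble(feature = names(baseline), percentage = unname(baseline))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$percentile, y = .data$percentage,
                                  colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = bl,
                        ggplot2::aes(yintercept = .data$percentage,
                                     colour = .data$feature),
                        linetype = 2, alpha = 0.5) +
    ggplot2::labs(x = "score percentile", y = "% of windows") +
    ggplot2::theme_minimal()
}

#' Importance bar plot of a trained network
#'
#' @param x An `ann_result`.
#' @param ... Unused.
#' @return A ggplot of mean importance with one-sd error bars.
#' @export
plot_ann_importance <- function(x, ...) {
  stopifnot(inherits(x, "ann_result"))
  d <- x$importance %>% arrange(desc(.data$mean)) %>%
    mutate(feature = factor(.data$feature, levels = .data$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "relative importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
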