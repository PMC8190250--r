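#' Plot a ROC curve with its optimal cutpoint
#'
#' @param object A [roc_analysis()] object.
#' @param ... Unused.
#' @return A ggplot: the empirical ROC, the chance diagonal, and the
#'   closest-to-(0,1) operating point.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_analysis <- function(object, ...) {
  curve <- object$curve
  pt <- tibble::tibble(fpr = 1 - object$cutpoint$specificity,
                       tpr = object$cutpoint$sensitivity)
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = pt,
                        ggplot2::aes(x = .data$fpr, y = .data$tpr),
                        colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC of %s (AUC %.3f)", object$score_name,
                      object$auc),
      subtitle = sprintf("optimal cutpoint %g: se %.2f, sp %.2f",
                         object$cutpoint$cutpoint,
                         object$cutpoint$sensitivity,
                         object$cutpoint$specificity)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cumulative progression curves
#'
#' @param object A [km_progression()] object.
#' @param ... Unused.
#' @return A ggplot of the cumulative probability of progression to the
#'   severe cluster against age, one step curve per risk group.
#' @exportS3Method ggplot2::autoplot
autoplot.km_progression <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$cum_progression,
                               colour = .data$group)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Age (years)",
                  y = "Cumulative probability of severe evolution",
                  colour = "Risk group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Silhouette plot for a two-cluster severity partition
#'
#' @param scores Numeric severity totals.
#' @param labels Two-cluster labels as in [silhouette_1d()].
#' @return A ggplot bar chart of per-patient silhouette widths, grouped and
#'   sorted within cluster.
#' @export
plot_silhouette <- function(scores, labels) {
  sil <- silhouette_1d(scores, labels)
  d <- dplyr::arrange(sil$widths, .data$label,
                      dplyr::desc(.data$silhouette))
  d$idx <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$silhouette,
                                  fill = factor(.data$label))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Silhouette width", fill = "Cluster",
                  subtitle = sprintf("mean width %.2f", sil$mean)) +
    ggplot2::theme_minimal()
}
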