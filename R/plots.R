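#' GSEA running-sum plot
#'
#' @param object A `gsea_es` from [enrichment_score()].
#' @param ... Unused.
#' @return A ggplot: the running sum over ranked positions with hit ticks.
#' @export
autoplot.gsea_es <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$walk)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b", colour = "#d95f02") +
    ggplot2::labs(x = "Rank in ordered gene list", y = "Running enrichment score",
                  title = sprintf("ES = %.3f", object$es)) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object An `auc_result` from [cv_feature_auc()].
#' @param ... Unused.
#' @return A ggplot of the cross-validated ROC curve.
#' @export
autoplot.auc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s: AUC = %.3f", object$feature, object$auc)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a DE table
#'
#' @param table A `de_table` or `meta_de_table`.
#' @param p_threshold,fc_threshold Thresholds drawn as guide lines; features
#'   passing both are highlighted.
#' @return A ggplot.
#' @export
plot_volcano <- function(table, p_threshold = 0.05, fc_threshold = NULL) {
  fc_cut <- if (is.null(fc_threshold)) 0 else log2(fc_threshold)
  df <- dplyr::mutate(
    tibble::as_tibble(table),
    called = .data$p < p_threshold & abs(.data$log2fc) >= fc_cut
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                        y = -log10(.data$p),
                                        colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02",
                                            `FALSE` = "grey50"),
                                 guide = "none") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
  if (!is.null(fc_threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = c(-fc_cut, fc_cut), linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
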