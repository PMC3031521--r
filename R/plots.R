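#' Plot a ROC curve
#'
#' @param object A [roc_curve()] object.
#' @param ... Unused.
#' @return A ggplot: TPR against FPR with the chance diagonal and the AUC
#'   in the subtitle.
#' @method autoplot mito_roc
#' @export
autoplot.mito_roc <- function(object, ...) {
  df <- as_tibble(object)
  df <- arrange(df, .data$fpr, .data$tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv", colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "ROC of integrated mitochondrial classifier",
      subtitle = sprintf("AUC = %.3f", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot integrated score distributions by gold-standard class
#'
#' @param scores A [integrate_evidence()] tibble.
#' @param catalog Catalog tibble supplying the labels.
#' @param threshold Optional log10-LR threshold drawn as a vertical line.
#' @return A ggplot of the per-class log10-LR densities.
#' @export
plot_score_distribution <- function(scores, catalog, threshold = NULL) {
  catalog <- validate_catalog(catalog)
  df <- inner_join(as_tibble(scores), catalog[, c("protein_id", "label")],
                   by = "protein_id")
  df <- df[df$label %in% c("positive", "negative"), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log_lr, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "summed log10 likelihood ratio", y = "density",
                  fill = "gold standard") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot an enrichment table
#'
#' @param enrichment A [hypergeom_enrichment()] tibble.
#' @param max_terms Show at most this many top terms. Default 20.
#' @return A ggplot bar chart of -log10 adjusted p-values.
#' @export
plot_enrichment <- function(enrichment, max_terms = 20) {
  df <- head(enrichment, max_terms)
  df$term_id <- factor(df$term_id, levels = rev(df$term_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q), y = .data$term_id)) +
    ggplot2::geom_col(fill = "#B2182B") +
    ggplot2::labs(x = expression(-log[10] ~ "BH-adjusted p"), y = NULL,
                  title = "Term overrepresentation in stress subnetwork") +
    ggplot2::theme_minimal()
}
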