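#' Heatmap of a CIN metric correlation matrix
#'
#' Tile heatmap of the Spearman correlations with rows and columns in
#' complete-linkage / Euclidean-distance leaf order.
#'
#' @param object A `"cin_cor"` matrix from [metric_correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cin_cor <- function(object, ...) {
  m <- unclass(object)
  ord <- cluster_order(m)
  labels <- rownames(m)[ord]
  long <- tidy(object)
  long$metric_a <- factor(long$metric_a, levels = labels)
  long$metric_b <- factor(long$metric_b, levels = labels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric_a, y = .data$metric_b,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman\nrho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Metric distributions by cohort and sample class
#'
#' @param scores Scores tibble joined to `cancer_type` and `class`.
#' @param metrics Metric columns to show.
#' @return A ggplot object (boxplots faceted by metric).
#' @export
plot_metric_distributions <- function(scores, metrics = cin_metric_names()) {
  long <- tidyr::pivot_longer(
    filter(scores, .data$class %in% c("tumor", "non_tumor")),
    all_of(metrics), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cancer_type, y = .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Top associations per metric and contrast
#'
#' Bar chart of -log10 Bonferroni-adjusted p-values for the ranked
#' cohorts from [top_k()].
#'
#' @param ranked A tibble from [top_k()].
#' @param alpha Significance level drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_top_associations <- function(ranked, alpha = 0.05) {
  ggplot2::ggplot(ranked,
                  ggplot2::aes(x = stats::reorder(.data$cancer_type,
                                                  -.data$p_adjusted),
                               y = -log10(.data$p_adjusted))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        colour = "#B2182B") +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(metric ~ contrast, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(-log[10]~adjusted~italic(p))) +
    ggplot2::theme_minimal()
}
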