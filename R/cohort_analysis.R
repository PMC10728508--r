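#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), the standard
#' Spearman convention. Requires at least three paired observations and at
#' least two distinct values in each vector.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort("spearman_rho(): vectors must have equal length")
  }
  if (length(x) < 3) {
    abort("spearman_rho(): need at least 3 observations")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("spearman_rho(): inputs must be finite")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("spearman_rho(): correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

new_cin_cor <- function(mat, n_samples) {
  structure(mat, class = c("cin_cor", class(mat)), n_samples = n_samples)
}

#' Spearman correlation matrix among the CIN metrics
#'
#' @param scores A scores tibble (as from [cin_scores()]), optionally
#'   pre-filtered to the samples of interest.
#' @param metrics Metric columns to correlate (default all six).
#' @return A symmetric matrix of class `"cin_cor"` with unit diagonal and
#'   an `n_samples` attribute; see [tidy()] / [glance()] / [autoplot()]
#'   methods.
#' @export
metric_correlation_matrix <- function(scores, metrics = cin_metric_names()) {
  missing_cols <- setdiff(metrics, names(scores))
  if (length(missing_cols)) {
    abort(paste0("scores table lacks metric column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(scores) < 3) {
    abort(paste0("insufficient data: need >= 3 samples, got ", nrow(scores)))
  }
  m <- as.matrix(scores[metrics])
  constant <- vapply(metrics, function(k) length(unique(m[, k])) < 2, logical(1))
  if (any(constant)) {
    abort(paste0("correlation undefined: constant metric(s): ",
                 paste(metrics[constant], collapse = ", ")))
  }
  rho <- stats::cor(m, method = "spearman")
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  new_cin_cor(rho, n_samples = nrow(scores))
}

#' Per-cohort Spearman correlation matrices
#'
#' Computes [metric_correlation_matrix()] within each cancer type,
#' restricted to tumor samples when a `class` column is present. Cohorts
#' with fewer than `min_samples` eligible samples are skipped with a
#' warning.
#'
#' @param scores Scores tibble joined to at least `cancer_type` (and
#'   optionally `class`).
#' @param metrics Metric columns to correlate.
#' @param min_samples Minimum samples per cohort (default 3).
#' @return Named list of `"cin_cor"` matrices, one per retained cohort.
#' @export
per_cohort_correlations <- function(scores, metrics = cin_metric_names(),
                                    min_samples = 3) {
  if (!"cancer_type" %in% names(scores)) {
    abort("per_cohort_correlations(): scores must carry a cancer_type column")
  }
  if ("class" %in% names(scores)) {
    scores <- filter(scores, .data$class == "tumor")
  }
  pieces <- split(scores, scores$cancer_type)
  keep <- vapply(pieces, nrow, integer(1)) >= min_samples
  if (any(!keep)) {
    warn(paste0("skipping cohort(s) with fewer than ", min_samples,
                " tumor samples: ", paste(names(pieces)[!keep], collapse = ", ")))
  }
  lapply(pieces[keep], metric_correlation_matrix, metrics = metrics)
}

#' Leaf order from complete-linkage hierarchical clustering
#'
#' Agglomerative clustering of the rows of a numeric matrix using complete
#' linkage on pairwise Euclidean distances, as used to order heatmap rows.
#' Deterministic given the input.
#'
#' @param m Numeric matrix (or data frame) of observations in rows.
#' @return Integer permutation of `seq_len(nrow(m))` giving the dendrogram
#'   leaf order.
#' @export
cluster_order <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) {
    abort("cluster_order(): need at least 2 rows")
  }
  if (!all(is.finite(m))) {
    abort("cluster_order(): entries must be finite")
  }
  if (nrow(m) == 2) {
    return(1:2)
  }
  stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")$order
}

#' Summarise metric distributions by cohort and sample class
#'
#' Per (cancer type, metric, tumor/non-tumor class): sample count, median,
#' and quartiles (linear interpolation). Samples of unknown class are
#' excluded.
#'
#' @param scores Scores tibble joined to `cancer_type` and `class`.
#' @param metrics Metric columns to summarise.
#' @return A tibble with columns `cancer_type`, `metric`, `class`, `n`,
#'   `median`, `q25`, `q75`.
#' @export
summarize_distributions <- function(scores, metrics = cin_metric_names()) {
  for (col in c("cancer_type", "class")) {
    if (!col %in% names(scores)) {
      abort(paste0("summarize_distributions(): missing column '", col, "'"))
    }
  }
  scores |>
    filter(.data$class %in% c("tumor", "non_tumor")) |>
    tidyr::pivot_longer(all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    group_by(.data$cancer_type, .data$metric, .data$class) |>
    summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      q25 = stats::quantile(.data$value, 0.25, names = FALSE, type = 7),
      q75 = stats::quantile(.data$value, 0.75, names = FALSE, type = 7),
      .groups = "drop"
    )
}

#' @exportS3Method generics::tidy
tidy.cin_cor <- function(x, ...) {
  labels <- rownames(x)
  tibble(
    metric_a = rep(labels, times = length(labels)),
    metric_b = rep(labels, each = length(labels)),
    rho = as.vector(unclass(x))
  )
}

#' @exportS3Method generics::glance
glance.cin_cor <- function(x, ...) {
  m <- unclass(x)
  off <- m[upper.tri(m)]
  tibble(
    n_samples = attr(x, "n_samples"),
    n_metrics = nrow(m),
    min_rho = min(off),
    max_rho = max(off),
    mean_abs_rho = mean(abs(off))
  )
}

#' @export
print.cin_cor <- function(x, ...) {
  cat("Spearman correlation among CIN metrics (n = ",
      attr(x, "n_samples"), " samples)\n", sep = "")
  m <- unclass(x)
  attr(m, "n_samples") <- NULL
  print(round(m, 3))
  invisible(x)
}
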