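#' Mann-Whitney U test (two-sided)
#'
#' U counts pairs where a value of group `a` exceeds one of group `b`,
#' with ties half-counted. The p-value is exact (from the null
#' distribution of U) when the combined sample size is at most 12 and
#' there are no ties; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used. When both groups are
#' constant and equal the statistic carries no information and p = 1 is
#' returned with a warning.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_max Combined sample size at or below which the exact null
#'   distribution is used (default 12; ignored in the presence of ties).
#' @return A list with elements `u_statistic`, `p_value`, `n_a`, `n_b`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b, exact_max = 12) {
  if (length(a) == 0 || length(b) == 0) {
    abort("mann_whitney_u(): both groups must be non-empty")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort("mann_whitney_u(): inputs must be finite")
  }
  n_a <- length(a)
  n_b <- length(b)
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  n <- n_a + n_b
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n <= exact_max) {
    # two-sided exact p: twice the smaller tail of the null distribution
    lower <- stats::pwilcox(u, n_a, n_b)
    upper <- stats::pwilcox(n_a * n_b - u, n_a, n_b)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tab <- table(c(a, b))
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      warn("mann_whitney_u(): zero variance (all values tied); p = 1")
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(u_statistic = u, p_value = p, n_a = n_a, n_b = n_b, method = method)
}

#' Bonferroni adjustment
#'
#' @param p Vector of raw p-values in (0, 1].
#' @param family_size Number of tests in the family; must be at least
#'   `length(p)`.
#' @return `pmin(1, p * family_size)`.
#' @export
bonferroni <- function(p, family_size) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("bonferroni(): p-values must lie in (0, 1]")
  }
  if (family_size < length(p)) {
    abort("bonferroni(): family_size must be >= length(p)")
  }
  stats::p.adjust(p, method = "bonferroni", n = family_size)
}

# The four clinical contrasts: variable and the two group labels
# (group a vs group b).
contrast_spec <- function(contrast) {
  switch(contrast,
    T4_vs_T1 = list(var = "t_stage", a = "T4", b = "T1"),
    M1_vs_M0 = list(var = "m_stage", a = "M1", b = "M0"),
    N1_vs_N0 = list(var = "n_stage", a = "N1", b = "N0"),
    sex = list(var = "sex", a = "female", b = "male"),
    abort(paste0("unknown contrast: ", contrast))
  )
}

empty_test_results <- function() {
  tibble(metric = character(), cancer_type = character(),
         contrast = character(), group_a = character(), group_b = character(),
         n_a = integer(), n_b = integer(), u_statistic = numeric(),
         p_raw = numeric(), p_adjusted = numeric(), direction = numeric())
}

#' Rank-based association of each metric with a clinical contrast
#'
#' Per cancer type, compares each metric between the two contrast groups
#' (T4 vs T1, M1 vs M0, N1 vs N0, or female vs male) with
#' [mann_whitney_u()]. Only tumor samples are used when a `class` column
#' is present. Cohorts where either group has fewer than `min_group_size`
#' samples are skipped and listed in the `"skipped"` attribute of the
#' result. Bonferroni correction is applied within the family of cohorts
#' tested for each (metric, contrast) pair, matching a per-panel "top-k
#' cohorts" presentation; pass `family_size` to widen the family.
#'
#' @param data Tibble with one row per sample: metric columns plus
#'   `cancer_type`, the contrast variable (`t_stage`, `m_stage`,
#'   `n_stage`, or `sex`), and optionally `class`.
#' @param contrast One of `"T4_vs_T1"`, `"M1_vs_M0"`, `"N1_vs_N0"`,
#'   `"sex"`.
#' @param min_group_size Minimum per-group sample count (default 3).
#' @param metrics Metric columns to test.
#' @param family_size Optional override of the Bonferroni family size;
#'   defaults to the number of cohorts tested.
#' @return A tibble with one row per (metric, cohort): `metric`,
#'   `cancer_type`, `contrast`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `u_statistic`, `p_raw`, `p_adjusted`, `direction` (sign of the
#'   group-a minus group-b median difference). Attribute `"skipped"` holds
#'   a tibble of cohorts not tested and why.
#' @export
run_contrast <- function(data,
                         contrast = c("T4_vs_T1", "M1_vs_M0", "N1_vs_N0", "sex"),
                         min_group_size = 3,
                         metrics = cin_metric_names(),
                         family_size = NULL) {
  contrast <- match.arg(contrast)
  cs <- contrast_spec(contrast)
  for (col in c("cancer_type", cs$var)) {
    if (!col %in% names(data)) {
      abort(paste0("run_contrast(): missing column '", col, "'"))
    }
  }
  if ("class" %in% names(data)) {
    data <- filter(data, .data$class == "tumor")
  }
  cohorts <- sort(unique(data$cancer_type))
  rows <- list()
  skipped <- list()
  for (ct in cohorts) {
    sub <- data[data$cancer_type == ct, ]
    va <- sub[!is.na(sub[[cs$var]]) & sub[[cs$var]] == cs$a, ]
    vb <- sub[!is.na(sub[[cs$var]]) & sub[[cs$var]] == cs$b, ]
    if (nrow(va) < min_group_size || nrow(vb) < min_group_size) {
      skipped[[length(skipped) + 1L]] <- tibble(
        cancer_type = ct, contrast = contrast,
        reason = sprintf("group sizes %s=%d, %s=%d below minimum %d",
                         cs$a, nrow(va), cs$b, nrow(vb), min_group_size))
      next
    }
    for (metric in metrics) {
      mw <- mann_whitney_u(va[[metric]], vb[[metric]])
      rows[[length(rows) + 1L]] <- tibble(
        metric = metric, cancer_type = ct, contrast = contrast,
        group_a = cs$a, group_b = cs$b,
        n_a = mw$n_a, n_b = mw$n_b, u_statistic = mw$u_statistic,
        p_raw = mw$p_value, p_adjusted = NA_real_,
        direction = sign(stats::median(va[[metric]]) -
                           stats::median(vb[[metric]])))
    }
  }
  skipped <- if (length(skipped)) bind_rows(skipped) else
    tibble(cancer_type = character(), contrast = character(),
           reason = character())
  if (!length(rows)) {
    out <- empty_test_results()
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- bind_rows(rows)
  fam <- family_size %||% length(unique(out$cancer_type))
  out <- out |>
    group_by(.data$metric) |>
    mutate(p_adjusted = bonferroni(.data$p_raw, fam)) |>
    ungroup()
  attr(out, "skipped") <- skipped
  attr(out, "family_size") <- fam
  out
}

#' Cohorts excluded from the sex contrast by default
#'
#' Cancer types occurring predominantly in one biological sex, where a
#' between-sex comparison is not meaningful.
#'
#' @return Character vector of cohort codes.
#' @export
single_sex_cohorts <- function() {
  c("CESC", "OV", "PRAD", "TGCT", "UCEC", "UCS")
}

#' Sex contrast across cohorts
#'
#' [run_contrast()] with `contrast = "sex"` after removing cohorts that
#' occur predominantly in one sex (see [single_sex_cohorts()]).
#'
#' @inheritParams run_contrast
#' @param excluded_cohorts Cohort codes removed before testing.
#' @return As [run_contrast()].
#' @export
run_sex_contrast <- function(data,
                             excluded_cohorts = single_sex_cohorts(),
                             min_group_size = 3,
                             metrics = cin_metric_names(),
                             family_size = NULL) {
  data <- filter(data, !.data$cancer_type %in% excluded_cohorts)
  run_contrast(data, contrast = "sex", min_group_size = min_group_size,
               metrics = metrics, family_size = family_size)
}

#' Top-k cohorts per metric and contrast
#'
#' For each (metric, contrast) pair, the `k` test results with the
#' smallest Bonferroni-adjusted p-values; ties broken by smaller raw p,
#' then cohort label. Fewer than `k` available results are all returned.
#'
#' @param results A test-result tibble from [run_contrast()].
#' @param k Number of cohorts to keep per panel (default 10).
#' @return Subset of `results`, ordered within each (metric, contrast).
#' @export
top_k <- function(results, k = 10) {
  stopifnot(k >= 1)
  results |>
    group_by(.data$metric, .data$contrast) |>
    arrange(.data$p_adjusted, .data$p_raw, .data$cancer_type,
            .by_group = TRUE) |>
    slice_head(n = k) |>
    ungroup()
}
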