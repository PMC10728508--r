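# Independent oracles and fixture builders. Everything here is written as
# deliberately naive loops, kept separate from the package's vectorised
# implementations so the two routes stay independent.

seg_fixture <- function(sample_id, chromosome, start, end, seg_mean) {
  tibble::tibble(sample_id = sample_id, chromosome = as.character(chromosome),
                 start = start, end = end, num_probes = NA_integer_,
                 seg_mean = seg_mean)
}

# Random single-sample segment table, independent of the package generator.
# Rounded means create ties and values sitting exactly on the threshold.
random_segments <- function(sample_id = "S1", chroms = c("1", "2", "3"),
                            max_seg = 8) {
  parts <- lapply(chroms, function(ch) {
    nseg <- sample(1:max_seg, 1)
    len <- sample(50:500, nseg, replace = TRUE)
    ends <- cumsum(len)
    tibble::tibble(sample_id = sample_id, chromosome = ch,
                   start = ends - len + 1, end = ends,
                   num_probes = NA_integer_,
                   seg_mean = round(stats::runif(nseg, -1, 1), 2))
  })
  do.call(rbind, parts)
}

# Naive per-segment loop evaluation of all six metrics for one sample.
oracle_metrics <- function(segments, t = 0.2, d = 0.2, aberrant_only = TRUE) {
  ord <- order(match(segments$chromosome, cinscores::chromosome_levels()),
               segments$start)
  segments <- segments[ord, ]
  n <- nrow(segments)
  len <- segments$end - segments$start + 1
  m <- segments$seg_mean
  ab <- abs(m) >= t

  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (!aberrant_only || ab[i]) {
      num <- num + len[i] * m[i]
      den <- den + len[i]
    }
  }
  tai_val <- if (den > 0) num / den else 0

  num2 <- 0; den2 <- 0
  for (i in seq_len(n)) {
    num2 <- num2 + len[i] * abs(m[i])
    den2 <- den2 + len[i]
  }

  cna_val <- 0
  for (i in seq_len(n)) {
    if (!ab[i]) next
    ok <- TRUE
    if (i > 1 && segments$chromosome[i - 1] == segments$chromosome[i] &&
        !(abs(m[i] - m[i - 1]) > d)) ok <- FALSE
    if (i < n && segments$chromosome[i + 1] == segments$chromosome[i] &&
        !(abs(m[i] - m[i + 1]) > d)) ok <- FALSE
    if (ok) cna_val <- cna_val + 1
  }

  bs <- 0
  for (i in seq_len(n)) if (ab[i]) bs <- bs + len[i]

  list(tai = tai_val, modified_tai = num2 / den2, cna = cna_val,
       break_points = 2 * sum(ab), base_segments = bs, fga = bs / sum(len))
}

# Two-sided Mann-Whitney p by full enumeration of label assignments.
enum_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_of(a, b)
  idx <- utils::combn(n, n_a)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= obs + 1e-9), mean(us >= obs - 1e-9)))
}

# Mid-ranks and Pearson on them, all by explicit counting.
midranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

rank_pearson <- function(x, y) {
  rx <- midranks(x)
  ry <- midranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Join scores to the simulated truth columns the association tests need.
join_truth <- function(scores, cohort) {
  dplyr::left_join(
    scores,
    cohort$truth[, c("sample_id", "cancer_type", "class", "t_stage",
                     "n_stage", "m_stage", "sex")],
    by = "sample_id")
}
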