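#' Configuration for the chromosomal-instability metrics
#'
#' @param aberration_threshold Non-negative log2-ratio magnitude `t` at or
#'   above which a segment counts as aberrant (default 0.2, the
#'   conventional cut for SNP-array segment means).
#' @param adjacency_difference Non-negative log2-ratio difference `d` that
#'   a segment must exceed against each same-chromosome neighbour to count
#'   towards the CNA metric (default 0.2).
#' @param tai_aberrant_only If `TRUE` (default) the total aberration index
#'   averages over aberrant segments only; if `FALSE` it averages over all
#'   segments.
#' @param length_convention `"inclusive"` (default; length = end - start
#'   + 1, matching 1-based inclusive SEG coordinates) or `"half_open"`
#'   (length = end - start).
#' @return A list of class `"metric_config"`.
#' @export
metric_config <- function(aberration_threshold = 0.2,
                          adjacency_difference = 0.2,
                          tai_aberrant_only = TRUE,
                          length_convention = c("inclusive", "half_open")) {
  length_convention <- match.arg(length_convention)
  stopifnot(is.numeric(aberration_threshold), aberration_threshold >= 0,
            is.numeric(adjacency_difference), adjacency_difference >= 0,
            is.logical(tai_aberrant_only), length(tai_aberrant_only) == 1L)
  structure(
    list(aberration_threshold = aberration_threshold,
         adjacency_difference = adjacency_difference,
         tai_aberrant_only = tai_aberrant_only,
         length_convention = length_convention),
    class = "metric_config"
  )
}

# Common preparation for the single-sample metric functions: enforce one
# sample, sort, and attach lengths / aberration flags / neighbour diffs.
prepare_one_sample <- function(segments, config) {
  if (is.null(segments) || nrow(segments) == 0) {
    abort("metric undefined for an empty segment list")
  }
  if ("sample_id" %in% names(segments) &&
      length(unique(segments$sample_id)) > 1L) {
    abort("single-sample metric called with segments from multiple samples")
  }
  segments <- segments[order(match(segments$chromosome, chromosome_levels()),
                             segments$start), ]
  annotate_segments(segments, config)
}

# Vectorised annotation used by both the single-sample functions and
# cin_scores(): length, aberrance, and adjacency separation within each
# (sample, chromosome) run. Assumes canonical sort order.
annotate_segments <- function(segments, config) {
  t <- config$aberration_threshold
  d <- config$adjacency_difference
  len <- segment_length(segments$start, segments$end, config$length_convention)
  ab <- abs(segments$seg_mean) >= t
  key <- if ("sample_id" %in% names(segments)) {
    paste(segments$sample_id, segments$chromosome, sep = "\r")
  } else {
    segments$chromosome
  }
  m <- segments$seg_mean
  nseg <- length(m)
  prev_diff <- c(NA_real_, abs(m[-1] - m[-nseg]))
  prev_diff[c(TRUE, key[-1] != key[-nseg])] <- NA_real_
  next_diff <- c(prev_diff[-1], NA_real_)
  # a missing neighbour (chromosome end) imposes no constraint
  sep <- ab &
    (is.na(prev_diff) | prev_diff > d) &
    (is.na(next_diff) | next_diff > d)
  segments$.len <- len
  segments$.ab <- ab
  segments$.sep <- sep
  segments
}

#' Total aberration index (TAI)
#'
#' Length-weighted mean of the signed segment means, interpretable as the
#' deviation from the neutral copy-number state averaged along the
#' genome. By default the average runs over aberrant segments only
#' (`|seg_mean| >= t`); with `tai_aberrant_only = FALSE` it runs over all
#' segments. Returns 0 when the averaging set is empty, so a flat profile
#' scores 0 rather than NaN.
#'
#' @param segments Segment tibble for a single sample.
#' @param config A [metric_config()].
#' @return A single signed real value.
#' @export
tai <- function(segments, config = metric_config()) {
  s <- prepare_one_sample(segments, config)
  use <- if (config$tai_aberrant_only) s$.ab else rep(TRUE, nrow(s))
  den <- sum(s$.len[use])
  if (den <= 0) return(0)
  sum(s$.len[use] * s$seg_mean[use]) / den
}

#' Modified total aberration index
#'
#' As [tai()], but over the absolute segment means of *all* segments,
#' removing directionality: gains and losses no longer cancel.
#'
#' @inheritParams tai
#' @return A single non-negative real value.
#' @export
modified_tai <- function(segments, config = metric_config()) {
  s <- prepare_one_sample(segments, config)
  sum(s$.len * abs(s$seg_mean)) / sum(s$.len)
}

#' Copy number abnormality (CNA) count
#'
#' Counts segments that are aberrant (`|seg_mean| >= t`) and whose segment
#' mean differs by more than `d` from every existing same-chromosome
#' neighbour; a missing neighbour at a chromosome end imposes no
#' constraint.
#'
#' @inheritParams tai
#' @return A non-negative integer.
#' @export
cna <- function(segments, config = metric_config()) {
  s <- prepare_one_sample(segments, config)
  sum(s$.sep)
}

#' Break-point count
#'
#' Two break points per aberrant segment (its two flanks), so the count is
#' always even.
#'
#' @inheritParams tai
#' @return A non-negative even integer.
#' @export
count_break_points <- function(segments, config = metric_config()) {
  s <- prepare_one_sample(segments, config)
  2L * sum(s$.ab)
}

#' Altered base count (base segments)
#'
#' Total number of bases lying in aberrant segments.
#'
#' @inheritParams tai
#' @return A non-negative integer in base-pair units.
#' @export
count_base_segments <- function(segments, config = metric_config()) {
  s <- prepare_one_sample(segments, config)
  sum(s$.len[s$.ab])
}

#' Fraction of genome altered (FGA)
#'
#' Altered bases divided by the total covered length of the sample.
#'
#' @inheritParams tai
#' @return A real value in \[0, 1\].
#' @export
fga <- function(segments, config = metric_config()) {
  s <- prepare_one_sample(segments, config)
  sum(s$.len[s$.ab]) / sum(s$.len)
}

#' Compute all six chromosomal-instability metrics per sample
#'
#' Applies [tai()], [modified_tai()], [cna()], [count_break_points()],
#' [count_base_segments()], and [fga()] to every sample in a segment
#' table, returning one row per sample. The computation is vectorised but
#' agrees exactly with the single-sample functions. Deterministic given
#' the input and configuration; the input record order does not matter.
#'
#' @param segments Segment tibble (multiple samples allowed), as from
#'   [read_segments()] or [simulate_cohort()].
#' @param config A [metric_config()].
#' @param validate If `TRUE` (default), run [validate_segments()] first
#'   and fail, naming offending samples, when the table is invalid.
#' @return A tibble with columns `sample_id` and the six metrics (see
#'   [cin_metric_names()]), one row per distinct sample, sorted by
#'   `sample_id`.
#' @export
cin_scores <- function(segments, config = metric_config(), validate = TRUE) {
  if (is.null(segments) || nrow(segments) == 0) {
    abort("cin_scores() called on an empty segment table")
  }
  if (validate) {
    v <- validate_segments(segments)
    if (nrow(v) > 0) {
      abort(paste0("segment table fails validation for sample(s): ",
                   paste(unique(head(v$sample_id, 5L)), collapse = ", "),
                   " (", nrow(v), " violation(s); see validate_segments())"))
    }
  }
  s <- annotate_segments(sort_segments(segments), config)
  aberrant_only <- config$tai_aberrant_only
  s |>
    group_by(.data$sample_id) |>
    summarise(
      tai = {
        use <- if (aberrant_only) .data$.ab else rep(TRUE, length(.data$.ab))
        den <- sum(.data$.len[use])
        if (den > 0) sum(.data$.len[use] * .data$seg_mean[use]) / den else 0
      },
      modified_tai = sum(.data$.len * abs(.data$seg_mean)) / sum(.data$.len),
      cna = sum(.data$.sep),
      break_points = 2L * sum(.data$.ab),
      base_segments = sum(.data$.len[.data$.ab]),
      fga = sum(.data$.len[.data$.ab]) / sum(.data$.len),
      .groups = "drop"
    ) |>
    arrange(.data$sample_id)
}
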