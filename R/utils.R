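#' Names of the six chromosomal-instability metrics
#'
#' @return Character vector of the metric column names produced by
#'   [cin_scores()], in their canonical order.
#' @export
cin_metric_names <- function() {
  c("tai", "modified_tai", "cna", "break_points", "base_segments", "fga")
}

#' Recognised chromosome labels, in genome order
#'
#' Autosomes 1-22 followed by X and Y. Segments on any other contig are
#' dropped on read with a warning.
#'
#' @return Character vector of length 24.
#' @export
chromosome_levels <- function() {
  c(as.character(1:22), "X", "Y")
}

# Strip an optional "chr" prefix and upper-case X/Y; returns labels as-is
# otherwise (validity is checked against chromosome_levels() by callers).
normalize_chromosome <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x[x == "x"] <- "X"
  x[x == "y"] <- "Y"
  x
}

# Segment length under the configured coordinate convention.
segment_length <- function(start, end, convention = "inclusive") {
  if (identical(convention, "half_open")) end - start else end - start + 1
}

#' Extract the patient identifier from a sample identifier
#'
#' TCGA-style barcodes encode the patient in a fixed-length prefix; the
#' default of 12 characters matches the project-participant portion of a
#' TCGA barcode (e.g. `"TCGA-A1-0001-01"` -> `"TCGA-A1-0001"`).
#'
#' @param sample_id Character vector of sample identifiers.
#' @param prefix_length Number of leading characters that identify the
#'   patient (default 12).
#' @return Character vector of patient identifiers.
#' @export
patient_of <- function(sample_id, prefix_length = 12) {
  substr(as.character(sample_id), 1L, prefix_length)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
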