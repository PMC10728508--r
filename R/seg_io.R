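#' Column-name mapping for SEG-dialect tables
#'
#' SEG files in the wild vary in their header names; a dialect maps the
#' logical fields to the column names actually present in the file. The
#' defaults match the masked copy-number tables distributed for TCGA
#' SNP-array profiles.
#'
#' @param sample,chromosome,start,end,num_probes,seg_mean Column names in
#'   the file for each logical field. `num_probes` is optional and may be
#'   absent from the file.
#' @return A named list usable as the `dialect` argument of
#'   [read_segments()].
#' @export
seg_dialect <- function(sample = "Sample", chromosome = "Chromosome",
                        start = "Start", end = "End",
                        num_probes = "Num_Probes",
                        seg_mean = "Segment_Mean") {
  list(sample = sample, chromosome = chromosome, start = start, end = end,
       num_probes = num_probes, seg_mean = seg_mean)
}

#' Read a segmented copy-number table
#'
#' Reads a tab-separated SEG-dialect file into a segment table: one row per
#' segment with columns `sample_id`, `chromosome`, `start`, `end`,
#' `num_probes`, `seg_mean`. Coordinates are 1-based inclusive. Chromosome
#' labels are accepted with or without a `chr` prefix and normalised;
#' records on contigs outside [chromosome_levels()] are dropped with a
#' warning. Rows violating record invariants (end before start, an
#' unparseable or non-finite numeric) raise an error naming the offending
#' file line(s). The result is sorted by sample, genome chromosome order,
#' then start position.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Column-name mapping from [seg_dialect()].
#' @return A tibble of segments satisfying the segment-table invariants.
#' @seealso [validate_segments()], [write_segments()]
#' @export
read_segments <- function(path, dialect = seg_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("segment file not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  required <- c("sample", "chromosome", "start", "end", "seg_mean")
  for (field in required) {
    if (!dialect[[field]] %in% names(raw)) {
      abort(paste0("missing required column '", dialect[[field]], "' in ", path))
    }
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1

  parse_num <- function(field) {
    x <- raw[[dialect[[field]]]]
    val <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(val))
    if (length(bad)) {
      abort(paste0("unparseable or missing numeric in column '",
                   dialect[[field]], "' at line(s) ",
                   paste(head(line_no[bad], 5L), collapse = ", ")))
    }
    val
  }

  start <- parse_num("start")
  end <- parse_num("end")
  seg_mean <- parse_num("seg_mean")

  bad_coord <- which(end < start)
  if (length(bad_coord)) {
    abort(paste0("segment end before start at line(s) ",
                 paste(head(line_no[bad_coord], 5L), collapse = ", ")))
  }
  bad_mean <- which(!is.finite(seg_mean))
  if (length(bad_mean)) {
    abort(paste0("non-finite segment mean at line(s) ",
                 paste(head(line_no[bad_mean], 5L), collapse = ", ")))
  }

  num_probes <- if (dialect$num_probes %in% names(raw)) {
    suppressWarnings(as.integer(raw[[dialect$num_probes]]))
  } else {
    rep(NA_integer_, nrow(raw))
  }

  chrom <- normalize_chromosome(raw[[dialect$chromosome]])
  keep <- chrom %in% chromosome_levels()
  if (any(!keep)) {
    warn(paste0("dropping ", sum(!keep), " segment(s) on unrecognised contig(s): ",
                paste(unique(chrom[!keep]), collapse = ", ")))
  }

  out <- tibble(
    sample_id = as.character(raw[[dialect$sample]]),
    chromosome = chrom,
    start = start,
    end = end,
    num_probes = num_probes,
    seg_mean = seg_mean
  )[keep, ]
  sort_segments(out)
}

# Canonical segment-table sort: sample, genome chromosome order, start.
sort_segments <- function(segments) {
  ord <- order(segments$sample_id,
               match(segments$chromosome, chromosome_levels()),
               segments$start)
  segments[ord, ]
}

#' Write a segment table in the SEG dialect
#'
#' Inverse of [read_segments()]: emits a tab-separated file whose header
#' follows `dialect`. A read-back through [read_segments()] reproduces
#' every field of a valid table.
#'
#' @param segments A segment tibble as produced by [read_segments()] or
#'   [simulate_cohort()].
#' @param path Output file path.
#' @param dialect Column-name mapping from [seg_dialect()].
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, dialect = seg_dialect()) {
  out <- tibble(
    !!dialect$sample := segments$sample_id,
    !!dialect$chromosome := segments$chromosome,
    !!dialect$start := segments$start,
    !!dialect$end := segments$end,
    !!dialect$num_probes := segments$num_probes,
    !!dialect$seg_mean := segments$seg_mean
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a segment table
#'
#' Checks the structural invariants every metric relies on: coordinates
#' ordered within each segment, finite segment means, recognised
#' chromosome labels, and no overlap between segments of the same sample
#' and chromosome. Violations are reported, not raised.
#'
#' @param segments A segment tibble.
#' @return A tibble of violations with columns `sample_id`, `chromosome`,
#'   `start`, `end`, `issue`; zero rows when the table is valid.
#' @export
validate_segments <- function(segments) {
  empty <- tibble(sample_id = character(), chromosome = character(),
                  start = numeric(), end = numeric(), issue = character())
  if (is.null(segments) || nrow(segments) == 0) {
    return(empty)
  }
  issues <- list()
  flag <- function(idx, what) {
    if (length(idx)) {
      issues[[length(issues) + 1L]] <<- tibble(
        sample_id = segments$sample_id[idx],
        chromosome = segments$chromosome[idx],
        start = segments$start[idx],
        end = segments$end[idx],
        issue = what
      )
    }
  }
  flag(which(segments$end < segments$start), "end before start")
  flag(which(!is.finite(segments$seg_mean)), "non-finite segment mean")
  flag(which(!segments$chromosome %in% chromosome_levels()),
       "unrecognised chromosome")

  sorted <- sort_segments(segments)
  grp <- paste(sorted$sample_id, sorted$chromosome, sep = "\r")
  same_grp <- grp[-1] == grp[-length(grp)]
  ov <- which(same_grp & sorted$start[-1] <= sorted$end[-nrow(sorted)]) + 1L
  if (length(ov)) {
    issues[[length(issues) + 1L]] <- tibble(
      sample_id = sorted$sample_id[ov],
      chromosome = sorted$chromosome[ov],
      start = sorted$start[ov],
      end = sorted$end[ov],
      issue = "overlaps previous segment"
    )
  }
  if (length(issues)) bind_rows(issues) else empty
}

#' Sample-type labels used for tumor / non-tumor classification
#'
#' The four non-tumor and six tumor sample-type labels, matched exactly
#' and case-sensitively by [classify_sample()].
#'
#' @return Character vector of labels.
#' @export
#' @rdname sample_class_labels
non_tumor_sample_labels <- function() {
  c("Blood Derived Normal", "Solid Tissue Normal",
    "Bone Marrow Normal", "Buccal Cell Normal")
}

#' @export
#' @rdname sample_class_labels
tumor_sample_labels <- function() {
  c("Metastatic", "Primary Blood Derived Cancer", "Primary Tumor",
    "Recurrent Tumor", "Additional - New Primary",
    "Primary Blood Derived Cancer - Peripheral Blood")
}

#' Classify sample-type labels as tumor or non-tumor
#'
#' Exact, case-sensitive match against the fixed label lists; anything
#' else (including `NA`) is `"unknown"`.
#'
#' @param label Character vector of sample-type labels.
#' @return Character vector with values `"tumor"`, `"non_tumor"`, or
#'   `"unknown"`.
#' @export
classify_sample <- function(label) {
  out <- rep("unknown", length(label))
  out[label %in% tumor_sample_labels()] <- "tumor"
  out[label %in% non_tumor_sample_labels()] <- "non_tumor"
  out
}

#' Collapse TNM stage labels to letter+digit form
#'
#' Keeps only the leading letter-plus-digit prefix of an AJCC stage label
#' ("T1a" -> "T1", "N0 (i-)" -> "N0"). 'X' stages (unassessable) and
#' empty values become `NA`. Labels that do not start with T, N, or M
#' followed by a digit or X become `NA` with a warning. Idempotent.
#'
#' @param x Character vector of raw stage labels.
#' @return Character vector of collapsed labels or `NA`.
#' @export
collapse_tnm <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  present <- !is.na(x) & nzchar(x)
  m <- regexpr("^[TNM][0-9X]", x)
  hit <- present & m == 1L
  pref <- substr(x[hit], 1L, 2L)
  pref[substr(pref, 2L, 2L) == "X"] <- NA_character_
  out[hit] <- pref
  bad <- present & !hit
  if (any(bad)) {
    warn(paste0("unrecognised stage label(s) treated as missing: ",
                paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

#' Read a per-patient clinical table
#'
#' Reads a tab-separated clinical table with one row per patient and
#' collapses the AJCC stage attributes via [collapse_tnm()]. The
#' `m_attribute` argument selects which metastasis column is used
#' (`"ajcc_pathologic_m"` in general, `"ajcc_clinical_m"` for the ACC
#' cohort). Missing stage or sex cells are recorded as `NA`, not errors.
#'
#' @param path Path to a tab-separated file with header columns
#'   `patient_id`, `cancer_type`, optionally `sample_type`,
#'   `ajcc_pathologic_t`, `ajcc_pathologic_n`, `ajcc_pathologic_m`,
#'   `ajcc_clinical_m`, and `gender`.
#' @param m_attribute Name of the column holding the metastasis stage.
#' @return A tibble with columns `patient_id`, `cancer_type`,
#'   `sample_type` (if present), `t_raw`, `n_raw`, `m_raw`, `t_stage`,
#'   `n_stage`, `m_stage`, `sex`.
#' @export
read_clinical <- function(path, m_attribute = "ajcc_pathologic_m") {
  if (!file.exists(path)) {
    abort(paste0("clinical file not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  for (col in c("patient_id", "cancer_type", m_attribute)) {
    if (!col %in% names(raw)) {
      abort(paste0("missing required column '", col, "' in ", path))
    }
  }
  dup <- unique(raw$patient_id[duplicated(raw$patient_id)])
  if (length(dup)) {
    abort(paste0("duplicate patient_id in clinical table: ",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  grab <- function(col) {
    if (col %in% names(raw)) as.character(raw[[col]]) else rep(NA_character_, nrow(raw))
  }
  sex <- tolower(grab("gender"))
  sex[!sex %in% c("female", "male")] <- NA_character_
  out <- tibble(
    patient_id = as.character(raw$patient_id),
    cancer_type = as.character(raw$cancer_type),
    t_raw = grab("ajcc_pathologic_t"),
    n_raw = grab("ajcc_pathologic_n"),
    m_raw = grab(m_attribute),
    sex = sex
  )
  if ("sample_type" %in% names(raw)) {
    out <- mutate(out, sample_type = as.character(raw$sample_type),
                  .after = "cancer_type")
  }
  mutate(out,
         t_stage = collapse_tnm(.data$t_raw),
         n_stage = collapse_tnm(.data$n_raw),
         m_stage = collapse_tnm(.data$m_raw))
}
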