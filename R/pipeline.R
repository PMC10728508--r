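#' End-to-end run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or
#'   `"seg_files"` (ingest SEG and clinical files).
#' @param sim A [simulation_config()] (simulate mode).
#' @param seg_files Character vector of SEG file paths (seg_files mode).
#' @param clinical_file Clinical table path (seg_files mode).
#' @param m_attribute Metastasis column for [read_clinical()].
#' @param sample_types Optional tibble (`sample_id`, `sample_type`)
#'   mapping samples to their type labels; when absent, the clinical
#'   table's `sample_type` is joined via the patient prefix.
#' @param dialect SEG column mapping from [seg_dialect()].
#' @param metrics A [metric_config()].
#' @param contrasts Clinical contrasts to test.
#' @param min_group_size Minimum per-group size for association tests.
#' @param excluded_sex_cohorts Cohorts removed from the sex contrast.
#' @param top_k Cohorts kept per (metric, contrast) panel.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the simulation seed.
#' @param skip_invalid If `TRUE`, samples with validation violations are
#'   dropped (and reported) instead of aborting the run.
#' @param prefix_length Patient-prefix length for [patient_of()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(mode = c("simulate", "seg_files"),
                       sim = simulation_config(),
                       seg_files = NULL,
                       clinical_file = NULL,
                       m_attribute = "ajcc_pathologic_m",
                       sample_types = NULL,
                       dialect = seg_dialect(),
                       metrics = metric_config(),
                       contrasts = c("T4_vs_T1", "M1_vs_M0", "N1_vs_N0", "sex"),
                       min_group_size = 3,
                       excluded_sex_cohorts = single_sex_cohorts(),
                       top_k = 10,
                       out_dir = tempfile("cin_run_"),
                       seed = NULL,
                       skip_invalid = FALSE,
                       prefix_length = 12) {
  mode <- match.arg(mode)
  if (mode == "seg_files" && (is.null(seg_files) || is.null(clinical_file))) {
    abort("seg_files mode requires seg_files and clinical_file")
  }
  structure(
    list(mode = mode, sim = sim, seg_files = seg_files,
         clinical_file = clinical_file, m_attribute = m_attribute,
         sample_types = sample_types, dialect = dialect, metrics = metrics,
         contrasts = contrasts, min_group_size = min_group_size,
         excluded_sex_cohorts = excluded_sex_cohorts, top_k = top_k,
         out_dir = out_dir, seed = seed, skip_invalid = isTRUE(skip_invalid),
         prefix_length = prefix_length),
    class = "run_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Write tab-separated result tables
#'
#' Writes each element of a named list of data frames to
#' `<directory>/<name>.tsv` with a header row, LF line endings, UTF-8
#' encoding, and empty cells for missing values.
#'
#' @param tables Named list of data frames.
#' @param directory Output directory (created if needed).
#' @return Character vector of file paths, named as `tables`.
#' @export
write_tables <- function(tables, directory) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(directory, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), path, na = "", progress = FALSE)
    paths[nm] <- path
  }
  paths
}

# Render the scores table for output: reals to 6 significant digits,
# counts as integers.
format_scores <- function(scores) {
  mutate(scores,
         across(c("tai", "modified_tai", "fga"), ~ signif(.x, 6)),
         across(c("cna", "break_points"), as.integer),
         # keep as numeric: genome-scale base counts can exceed .Machine$integer.max
         base_segments = round(.data$base_segments))
}

cor_long <- function(cm, cancer_type) {
  mutate(tidy(cm), cancer_type = cancer_type, .before = 1)
}

# Assemble segments + per-sample metadata (cancer_type, class, stages,
# sex) for either input mode.
ingest_inputs <- function(cfg) {
  if (cfg$mode == "simulate") {
    sim <- cfg$sim
    if (!is.null(cfg$seed)) sim$seed <- as.integer(cfg$seed)
    cohort <- simulate_cohort(sim)
    meta <- select(cohort$truth, "sample_id", "cancer_type", "class",
                   "t_stage", "n_stage", "m_stage", "sex")
    list(segments = cohort$segments, meta = meta, cohort = cohort)
  } else {
    segments <- bind_rows(lapply(cfg$seg_files, read_segments,
                                 dialect = cfg$dialect))
    segments <- sort_segments(segments)
    clinical <- read_clinical(cfg$clinical_file, m_attribute = cfg$m_attribute)
    samples <- tibble(sample_id = unique(segments$sample_id))
    samples$patient_id <- patient_of(samples$sample_id, cfg$prefix_length)
    if (!is.null(cfg$sample_types)) {
      samples <- left_join(samples, cfg$sample_types, by = "sample_id")
    } else if ("sample_type" %in% names(clinical)) {
      samples <- left_join(samples,
                           select(clinical, "patient_id", "sample_type"),
                           by = "patient_id")
    } else {
      samples$sample_type <- NA_character_
    }
    samples$class <- classify_sample(samples$sample_type)
    meta <- samples |>
      left_join(select(clinical, "patient_id", "cancer_type", "t_stage",
                       "n_stage", "m_stage", "sex"),
                by = "patient_id") |>
      select("sample_id", "cancer_type", "class", "t_stage", "n_stage",
             "m_stage", "sex")
    list(segments = segments, meta = meta, cohort = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Simulates or ingests a cohort, validates the segment table, computes
#' the six metrics per sample, summarises distributions by cohort and
#' class, computes pooled and per-cohort Spearman correlation matrices,
#' runs the clinical association tests with Bonferroni correction, ranks
#' the top-k cohorts per panel, and writes every result as a
#' tab-separated file plus a hashed manifest. Identical configuration and
#' seed yield identical output hashes.
#'
#' @param cfg A [run_config()].
#' @return The manifest tibble (`file`, `md5`, `bytes`), invisibly also
#'   written to `manifest.tsv` in the output directory.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- run_stage("ingest", ingest_inputs(cfg))
  segments <- inputs$segments
  meta <- inputs$meta

  report <- run_stage("validate", validate_segments(segments))
  if (nrow(report) > 0) {
    bad <- unique(report$sample_id)
    if (cfg$skip_invalid) {
      message("dropping ", length(bad), " invalid sample(s): ",
              paste(head(bad, 5L), collapse = ", "))
      segments <- filter(segments, !.data$sample_id %in% bad)
      if (nrow(segments) == 0) {
        abort("pipeline stage 'validate' failed: no valid samples remain")
      }
    } else {
      abort(paste0("pipeline stage 'validate' failed: invalid segments for ",
                   "sample(s): ", paste(head(bad, 5L), collapse = ", ")))
    }
  }

  scores <- run_stage("metrics", cin_scores(segments, cfg$metrics,
                                            validate = FALSE))
  scores_meta <- left_join(scores, meta, by = "sample_id")

  summaries <- run_stage("summaries", summarize_distributions(scores_meta))

  correlations <- run_stage("correlations", {
    tumor <- filter(scores_meta, .data$class == "tumor")
    parts <- list()
    if (nrow(tumor) >= 3) {
      parts[["ALL"]] <- cor_long(metric_correlation_matrix(tumor), "ALL")
    }
    by_cohort <- withCallingHandlers(
      per_cohort_correlations(scores_meta),
      warning = function(w) {
        message(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    for (ct in names(by_cohort)) {
      parts[[ct]] <- cor_long(by_cohort[[ct]], ct)
    }
    bind_rows(parts)
  })

  assoc <- run_stage("associations", {
    res <- list()
    skips <- list()
    for (ctr in cfg$contrasts) {
      r <- if (ctr == "sex") {
        run_sex_contrast(scores_meta,
                         excluded_cohorts = cfg$excluded_sex_cohorts,
                         min_group_size = cfg$min_group_size)
      } else {
        run_contrast(scores_meta, contrast = ctr,
                     min_group_size = cfg$min_group_size)
      }
      res[[ctr]] <- r
      skips[[ctr]] <- attr(r, "skipped")
    }
    list(results = bind_rows(res), skips = bind_rows(skips))
  })

  ranked <- run_stage("top_k", top_k(assoc$results, cfg$top_k))

  paths <- run_stage("write", write_tables(list(
    validation_report = report,
    cin_scores = format_scores(scores),
    distribution_summary = summaries,
    correlations = correlations,
    associations = assoc$results,
    association_skips = assoc$skips,
    top_associations = ranked
  ), cfg$out_dir))

  files <- sort(basename(paths))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))),
    bytes = file.size(file.path(cfg$out_dir, files))
  )
  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                   progress = FALSE)
  manifest
}
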