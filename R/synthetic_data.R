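#' Genome model for simulation
#'
#' @param chromosome Character vector of chromosome labels (must be drawn
#'   from [chromosome_levels()]).
#' @param length_bp Positive integer-valued lengths in base pairs.
#' @return A tibble with columns `chromosome`, `length_bp` and attribute
#'   `total_bp`.
#' @export
genome_model <- function(chromosome, length_bp) {
  stopifnot(length(chromosome) == length(length_bp),
            all(chromosome %in% chromosome_levels()),
            !anyDuplicated(chromosome),
            all(is.finite(length_bp)), all(length_bp >= 1))
  g <- tibble(chromosome = as.character(chromosome),
              length_bp = as.numeric(length_bp))
  attr(g, "total_bp") <- sum(g$length_bp)
  g
}

#' Default 22-autosome genome (~2.9 Gbp, rounded lengths)
#'
#' @return A [genome_model()].
#' @export
#' @rdname genomes
default_genome <- function() {
  lengths_mb <- c(249, 243, 198, 190, 182, 171, 159, 145, 138, 134, 135,
                  133, 114, 107, 102, 90, 83, 80, 59, 64, 47, 51)
  genome_model(as.character(1:22), lengths_mb * 1e6)
}

#' @description `toy_genome()` is a small 3-chromosome genome (240 Mbp)
#'   for fast tests and examples.
#' @export
#' @rdname genomes
toy_genome <- function() {
  genome_model(c("1", "2", "3"), c(100e6, 80e6, 60e6))
}

#' Parameterisation of a synthetic cohort
#'
#' Defines the generative model for SEG-shaped copy-number cohorts: per
#' chromosome, a Poisson number of breakpoints (rate `breakpoint_rate` per
#' Mb) placed uniformly tiles the chromosome into segments; each segment
#' is independently aberrant with probability `p_alt`. Aberrant segment
#' means are `s * max(min_alt_magnitude, alt_mean + alt_sd * z)` with sign
#' `s` uniform on \{-1, +1\} and `z` standard normal — the truncation keeps
#' "aberrant in truth" aligned with "aberrant by threshold". Neutral
#' segment means are `neutral_sd * z`.
#'
#' Covariate effects multiply `p_alt` (capped at 1) and/or `alt_mean` for
#' samples carrying the affected level: `tumor` applies to tumor samples,
#' `t_stage` to T4, `m_stage` to M1, `n_stage` to N1, and `sex` to male
#' patients.
#'
#' @param genome A [genome_model()] (default [default_genome()]).
#' @param cancer_types Cohort codes to simulate, one cohort each.
#' @param n_per_group Patients per level of each balanced clinical
#'   contrast; each cohort holds `2 * n_per_group` tumor samples.
#' @param breakpoint_rate Expected breakpoints per Mb per sample.
#' @param p_alt Baseline probability that a segment is aberrant.
#' @param alt_mean,alt_sd Location and spread of the aberrant amplitude.
#' @param neutral_sd Standard deviation of neutral segment means.
#' @param min_alt_magnitude Truncation floor of the aberrant magnitude.
#' @param effects Named list among `tumor`, `t_stage`, `m_stage`,
#'   `n_stage`, `sex`; each element a list with multiplicative `p_alt`
#'   and/or `alt_mean` entries.
#' @param paired_normal If `TRUE`, also emit a baseline-burden
#'   solid-tissue-normal sample per patient.
#' @param seed Integer seed; a fixed seed reproduces the cohort
#'   bit-exactly.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(genome = default_genome(),
                              cancer_types = "SYN1",
                              n_per_group = 50,
                              breakpoint_rate = 0.05,
                              p_alt = 0.1,
                              alt_mean = 0.5,
                              alt_sd = 0.1,
                              neutral_sd = 0.05,
                              min_alt_magnitude = 0.2,
                              effects = list(tumor = list(p_alt = 3)),
                              paired_normal = FALSE,
                              seed = 1L) {
  stopifnot(is.data.frame(genome), nrow(genome) >= 1,
            length(cancer_types) >= 1, n_per_group >= 1,
            breakpoint_rate >= 0, p_alt >= 0, p_alt <= 1,
            alt_sd >= 0, neutral_sd >= 0, min_alt_magnitude >= 0,
            is.list(effects), is.logical(paired_normal))
  bad <- setdiff(names(effects), c("tumor", "t_stage", "m_stage", "n_stage", "sex"))
  if (length(bad)) {
    abort(paste0("unknown effect name(s): ", paste(bad, collapse = ", ")))
  }
  for (e in effects) {
    vals <- unlist(e)
    if (length(vals) && (any(!is.finite(vals)) || any(vals < 0))) {
      abort("effect multipliers must be finite and non-negative")
    }
  }
  structure(
    list(genome = genome, cancer_types = as.character(cancer_types),
         n_per_group = as.integer(n_per_group),
         breakpoint_rate = breakpoint_rate, p_alt = p_alt,
         alt_mean = alt_mean, alt_sd = alt_sd, neutral_sd = neutral_sd,
         min_alt_magnitude = min_alt_magnitude, effects = effects,
         paired_normal = isTRUE(paired_normal), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Multiply baseline parameters by the active covariate effects.
apply_effects <- function(p_alt, alt_mean, effects, active) {
  for (nm in active) {
    e <- effects[[nm]]
    if (is.null(e)) next
    p_alt <- min(1, p_alt * (e[["p_alt"]] %||% 1))
    alt_mean <- alt_mean * (e[["alt_mean"]] %||% 1)
  }
  list(p_alt = p_alt, alt_mean = alt_mean)
}

#' Simulate one sample's segmented copy-number profile
#'
#' Uses the current RNG stream (seed control lives in
#' [simulate_cohort()]). Segments tile each chromosome exactly: disjoint,
#' sorted, covering every base.
#'
#' @param genome A [genome_model()].
#' @param sample_id Sample identifier for the emitted records.
#' @param p_alt,alt_mean,alt_sd,neutral_sd,breakpoint_rate,min_alt_magnitude
#'   Generative parameters; see [simulation_config()].
#' @return A segment tibble for one sample.
#' @export
simulate_sample <- function(genome, sample_id = "S1",
                            p_alt = 0.1, alt_mean = 0.5, alt_sd = 0.1,
                            neutral_sd = 0.05, breakpoint_rate = 0.05,
                            min_alt_magnitude = 0.2) {
  stopifnot(p_alt >= 0, p_alt <= 1, breakpoint_rate >= 0,
            alt_sd >= 0, neutral_sd >= 0)
  per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length_bp[i]
    k <- min(stats::rpois(1, breakpoint_rate * len / 1e6), len - 1)
    bp <- if (k > 0) sort(sample.int(len - 1L, k)) else integer(0)
    starts <- c(1, bp + 1)
    ends <- c(bp, len)
    ns <- length(starts)
    # draw aberration uniforms first so common-seed runs share aberration
    # calls across p_alt values (monotone coupling)
    ab <- stats::runif(ns) < p_alt
    sgn <- sample(c(-1, 1), ns, replace = TRUE)
    mag <- pmax(min_alt_magnitude, alt_mean + alt_sd * stats::rnorm(ns))
    neut <- neutral_sd * stats::rnorm(ns)
    list(chromosome = rep(genome$chromosome[i], ns),
         start = starts, end = ends,
         seg_mean = ifelse(ab, sgn * mag, neut))
  })
  tibble(
    sample_id = sample_id,
    chromosome = unlist(lapply(per_chrom, `[[`, "chromosome")),
    start = unlist(lapply(per_chrom, `[[`, "start")),
    end = unlist(lapply(per_chrom, `[[`, "end")),
    num_probes = NA_integer_,
    seg_mean = unlist(lapply(per_chrom, `[[`, "seg_mean"))
  )
}

#' Simulate a multi-cohort study
#'
#' For each cohort, `2 * n_per_group` tumor patients receive balanced
#' random assignments of T stage (T1/T4), nodal involvement (N0/N1),
#' metastasis (M0/M1), and sex, with covariate effects applied
#' multiplicatively to the generative parameters; with
#' `paired_normal = TRUE` each patient also contributes a baseline
#' solid-tissue-normal sample. Bit-exactly reproducible for a fixed seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `"simulated_cohort"` with elements `segments`
#'   (segment tibble), `clinical` (per-patient tibble in the clinical
#'   dialect of [read_clinical()]), `truth` (per-sample generating
#'   parameters and group assignments), and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    seg_parts <- list()
    truth_parts <- list()
    clin_parts <- list()
    for (ci in seq_along(cfg$cancer_types)) {
      ct <- cfg$cancer_types[ci]
      n <- 2L * cfg$n_per_group
      patient_id <- sprintf("TCGA-%02d-%04d", ci, seq_len(n))
      t_stage <- sample(rep(c("T1", "T4"), each = cfg$n_per_group))
      n_stage <- sample(rep(c("N0", "N1"), each = cfg$n_per_group))
      m_stage <- sample(rep(c("M0", "M1"), each = cfg$n_per_group))
      sex <- sample(rep(c("female", "male"), each = cfg$n_per_group))
      for (j in seq_len(n)) {
        active <- c("tumor",
                    if (t_stage[j] == "T4") "t_stage",
                    if (m_stage[j] == "M1") "m_stage",
                    if (n_stage[j] == "N1") "n_stage",
                    if (sex[j] == "male") "sex")
        pars <- apply_effects(cfg$p_alt, cfg$alt_mean, cfg$effects, active)
        sid <- paste0(patient_id[j], "-01")
        seg_parts[[length(seg_parts) + 1L]] <- simulate_sample(
          cfg$genome, sample_id = sid,
          p_alt = pars$p_alt, alt_mean = pars$alt_mean, alt_sd = cfg$alt_sd,
          neutral_sd = cfg$neutral_sd, breakpoint_rate = cfg$breakpoint_rate,
          min_alt_magnitude = cfg$min_alt_magnitude)
        truth_parts[[length(truth_parts) + 1L]] <- tibble(
          sample_id = sid, patient_id = patient_id[j], cancer_type = ct,
          sample_type = "Primary Tumor", class = "tumor",
          t_stage = t_stage[j], n_stage = n_stage[j], m_stage = m_stage[j],
          sex = sex[j], p_alt = pars$p_alt, alt_mean = pars$alt_mean)
        if (cfg$paired_normal) {
          nid <- paste0(patient_id[j], "-11")
          seg_parts[[length(seg_parts) + 1L]] <- simulate_sample(
            cfg$genome, sample_id = nid,
            p_alt = cfg$p_alt, alt_mean = cfg$alt_mean, alt_sd = cfg$alt_sd,
            neutral_sd = cfg$neutral_sd,
            breakpoint_rate = cfg$breakpoint_rate,
            min_alt_magnitude = cfg$min_alt_magnitude)
          truth_parts[[length(truth_parts) + 1L]] <- tibble(
            sample_id = nid, patient_id = patient_id[j], cancer_type = ct,
            sample_type = "Solid Tissue Normal", class = "non_tumor",
            t_stage = t_stage[j], n_stage = n_stage[j], m_stage = m_stage[j],
            sex = sex[j], p_alt = cfg$p_alt, alt_mean = cfg$alt_mean)
        }
      }
      clin_parts[[length(clin_parts) + 1L]] <- tibble(
        patient_id = patient_id, cancer_type = ct,
        sample_type = "Primary Tumor",
        ajcc_pathologic_t = t_stage, ajcc_pathologic_n = n_stage,
        ajcc_pathologic_m = m_stage, ajcc_clinical_m = m_stage,
        gender = sex)
    }
    structure(
      list(segments = sort_segments(bind_rows(seg_parts)),
           clinical = bind_rows(clin_parts),
           truth = bind_rows(truth_parts),
           config = cfg),
      class = "simulated_cohort"
    )
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated copy-number cohort:",
      length(unique(x$truth$sample_id)), "samples,",
      length(unique(x$truth$patient_id)), "patients,",
      length(unique(x$truth$cancer_type)), "cohort(s);",
      nrow(x$segments), "segments\n")
  invisible(x)
}

#' Expected aberrant genome fraction under the generative model
#'
#' Closed-form expectation of the fraction of the genome called aberrant
#' at threshold `t`: `p_eff * P(|aberrant mean| >= t) +
#' (1 - p_eff) * P(|neutral mean| >= t)`, with `p_eff` the group's
#' effective aberration probability. Segment lengths are independent of
#' aberration status, so the length-weighted FGA shares this expectation.
#'
#' @param cfg A [simulation_config()].
#' @param group Character vector of active effect names (subset of
#'   `names(cfg$effects)` plus `"tumor"` etc.); empty for baseline.
#' @param threshold Aberration threshold `t` of the metric configuration.
#' @return Expected FGA in \[0, 1\].
#' @export
expected_altered_fraction <- function(cfg, group = character(),
                                      threshold = 0.2) {
  pars <- apply_effects(cfg$p_alt, cfg$alt_mean, cfg$effects, group)
  p_neutral <- if (cfg$neutral_sd == 0) {
    as.numeric(threshold <= 0)
  } else {
    2 * stats::pnorm(-threshold / cfg$neutral_sd)
  }
  p_aberrant <- if (cfg$min_alt_magnitude >= threshold) {
    1
  } else if (cfg$alt_sd == 0) {
    as.numeric(pars$alt_mean >= threshold)
  } else {
    1 - stats::pnorm((threshold - pars$alt_mean) / cfg$alt_sd)
  }
  pars$p_alt * p_aberrant + (1 - pars$p_alt) * p_neutral
}
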