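test_that("zero breakpoint rate yields one segment per chromosome", {
  set.seed(1)
  g <- toy_genome()
  s <- simulate_sample(g, breakpoint_rate = 0)
  expect_equal(nrow(s), nrow(g))
  expect_equal(s$start, rep(1, nrow(g)))
  expect_equal(s$end, g$length_bp)
})

test_that("degenerate parameter settings force known metric values", {
  set.seed(2)
  flat <- simulate_sample(toy_genome(), p_alt = 0, neutral_sd = 0)
  sc <- cin_scores(flat)
  expect_equal(unlist(sc[cin_metric_names()]),
               c(tai = 0, modified_tai = 0, cna = 0, break_points = 0,
                 base_segments = 0, fga = 0))

  set.seed(3)
  allab <- simulate_sample(toy_genome(), p_alt = 1, neutral_sd = 0,
                           alt_mean = 0.5, alt_sd = 0)
  sc2 <- cin_scores(allab)
  expect_equal(sc2$fga, 1)
  expect_equal(sc2$modified_tai, 0.5)
})

test_that("simulated samples tile each chromosome exactly", {
  cohort <- simulate_cohort(simulation_config(genome = toy_genome(),
                                              n_per_group = 5, seed = 9,
                                              paired_normal = TRUE))
  expect_equal(nrow(validate_segments(cohort$segments)), 0)
  g <- toy_genome()
  per <- dplyr::summarise(
    dplyr::group_by(cohort$segments, sample_id, chromosome),
    covered = sum(end - start + 1), first = min(start), last = max(end),
    .groups = "drop")
  per <- dplyr::left_join(per, g, by = "chromosome")
  expect_true(all(per$covered == per$length_bp))
  expect_true(all(per$first == 1))
  expect_true(all(per$last == per$length_bp))
})

test_that("cohorts are reproducible by seed and vary across seeds", {
  cfg <- simulation_config(genome = toy_genome(), n_per_group = 4, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$segments, b$segments)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)

  cfg2 <- cfg
  cfg2$seed <- 124L
  c2 <- simulate_cohort(cfg2)
  expect_false(identical(a$segments, c2$segments))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(555)
  before <- rnorm(3)
  set.seed(555)
  invisible(simulate_cohort(simulation_config(genome = toy_genome(),
                                              n_per_group = 2, seed = 1)))
  expect_identical(rnorm(3), before)
})

test_that("covariate effects multiply the truth parameters", {
  cfg <- simulation_config(
    genome = toy_genome(), n_per_group = 4, seed = 5, p_alt = 0.1,
    effects = list(tumor = list(p_alt = 3), t_stage = list(p_alt = 2)))
  cohort <- simulate_cohort(cfg)
  t1 <- cohort$truth[cohort$truth$t_stage == "T1", ]
  t4 <- cohort$truth[cohort$truth$t_stage == "T4", ]
  expect_equal(unique(t1$p_alt), 0.3)        # tumor effect only
  expect_equal(unique(t4$p_alt), 0.6)        # tumor x stage
  expect_equal(nrow(t1), nrow(t4))           # balanced assignment

  null_cfg <- simulation_config(genome = toy_genome(), n_per_group = 4,
                                seed = 5, effects = list())
  null_truth <- simulate_cohort(null_cfg)$truth
  expect_equal(unique(null_truth$p_alt), 0.1)

  capped <- simulation_config(genome = toy_genome(), n_per_group = 2,
                              seed = 5, p_alt = 0.5,
                              effects = list(tumor = list(p_alt = 10)))
  expect_equal(unique(simulate_cohort(capped)$truth$p_alt), 1)
})

test_that("clinical and truth tables stay linked to the segments", {
  cohort <- simulate_cohort(simulation_config(genome = toy_genome(),
                                              n_per_group = 3, seed = 8,
                                              paired_normal = TRUE))
  sids <- unique(cohort$segments$sample_id)
  expect_setequal(sids, cohort$truth$sample_id)
  expect_setequal(patient_of(sids), cohort$clinical$patient_id)
  expect_equal(classify_sample(cohort$truth$sample_type), cohort$truth$class)
  # clinical stage labels collapse to themselves
  expect_equal(collapse_tnm(cohort$clinical$ajcc_pathologic_t),
               cohort$clinical$ajcc_pathologic_t)
})

test_that("raising p_alt never lowers base_segments under common random numbers", {
  for (seed in 1:5) {
    set.seed(seed)
    lo <- cin_scores(simulate_sample(toy_genome(), p_alt = 0.1))
    set.seed(seed)
    hi <- cin_scores(simulate_sample(toy_genome(), p_alt = 0.4))
    expect_gte(hi$base_segments, lo$base_segments)
  }
})

test_that("expected_altered_fraction handles degenerate settings in closed form", {
  cfg <- simulation_config(genome = toy_genome(), p_alt = 0.3,
                           neutral_sd = 0, alt_mean = 0.5, alt_sd = 0,
                           effects = list())
  expect_equal(expected_altered_fraction(cfg, threshold = 0.2), 0.3)

  cfg0 <- simulation_config(genome = toy_genome(), p_alt = 0,
                            neutral_sd = 0, effects = list())
  expect_equal(expected_altered_fraction(cfg0, threshold = 0.2), 0)

  # tumor effect triples the effective aberration probability
  cfg_t <- simulation_config(genome = toy_genome(), p_alt = 0.1,
                             neutral_sd = 0, alt_sd = 0,
                             effects = list(tumor = list(p_alt = 3)))
  expect_equal(expected_altered_fraction(cfg_t, group = "tumor",
                                         threshold = 0.2), 0.3)

  # neutral segments above threshold contribute the normal tail
  cfg_n <- simulation_config(genome = toy_genome(), p_alt = 0,
                             neutral_sd = 0.1, effects = list())
  expect_equal(expected_altered_fraction(cfg_n, threshold = 0.2),
               2 * pnorm(-2))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_config(p_alt = 1.5))
  expect_error(simulation_config(breakpoint_rate = -1))
  expect_error(simulation_config(effects = list(bogus = list(p_alt = 2))),
               "unknown effect")
  expect_error(simulation_config(effects = list(tumor = list(p_alt = -2))),
               "non-negative")
})
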