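---
title: "Scoring chromosomal instability from segmented copy-number data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromosomal instability from segmented copy-number data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinscores)
library(dplyr)
```

## Background and model

Chromosomal instability (CIN) in tumors manifests in copy-number data
as segments of the genome whose intensity deviates from the diploid
baseline. Given a segmented profile — per sample, a set of
non-overlapping intervals each carrying a segment mean $\bar y_i$ in
log2-ratio units and a length $d_i$ in base pairs — this package scores
CIN with six surrogates that emphasise different aspects of the
phenomenon. Writing $A = \{i : |\bar y_i| \ge t\}$ for the aberrant
segments at threshold $t$:

* **TAI** $= \sum_{i \in A} d_i \bar y_i \big/ \sum_{i \in A} d_i$ —
  the length-weighted *signed* deviation; amplifications and deletions
  cancel, so TAI carries directionality information the other scores
  discard.
* **Modified TAI** $= \sum_i d_i |\bar y_i| \big/ \sum_i d_i$ over
  *all* segments — total absolute deviation per covered base.
* **CNA** — the number of segments in $A$ whose mean differs by more
  than $d$ from every existing same-chromosome neighbour.
* **Break points** $= 2\,|A|$ — each aberrant segment contributes its
  two flanking breaks.
* **Base segments** $= \sum_{i \in A} d_i$ — altered bases.
* **FGA** $=$ base segments $/ \sum_i d_i$ — the altered fraction of
  the covered genome.

Downstream, cross-metric structure is summarised with Spearman
correlation matrices (pooled across tumor samples and within each
cancer type), ordered for display by complete-linkage hierarchical
clustering on Euclidean distances; and each metric is tested against
four clinical contrasts — T4 vs T1, M1 vs M0, N1 vs N0, and female vs
male — per cohort with a two-sided Mann–Whitney test, Bonferroni
correction, and a top-$k$ ranking of cohorts per (metric, contrast)
panel.

## Pinned formula conventions

Published descriptions of these scores leave several details open; the
package pins each of them, and every choice is exposed as a
configuration flag so an alternative convention is one argument away.

* **TAI averaging set.** Whether the signed average runs over aberrant
  segments only or over all segments varies between formulations.
  Default: aberrant only (`tai_aberrant_only = TRUE`), which makes TAI
  the signed counterpart of the aberrant burden; with the flag off, TAI
  over all segments satisfies $|\mathrm{TAI}| \le$ Modified TAI, with
  equality on sign-constant profiles (a tested invariant).
* **Empty aberrant set.** A flat profile would make TAI 0/0; the
  package returns 0 so normal genomes remain finite and comparable.
* **CNA neighbour rule.** A segment counts when it is aberrant *and*
  separated by strictly more than $d$ from each neighbour that exists;
  a chromosome end imposes no constraint. Both-neighbour separation
  (rather than any-neighbour) is the stricter reading of "adjacent
  segments must differ" and is what the implementation and its oracle
  tests pin down. Consequently `cna` is bounded above by the aberrant
  count, i.e. by half the break-point count.
* **Thresholds.** $t = d = 0.2$ log2-ratio units, the conventional
  aberration cut for SNP-array segment means. The aberration test is
  inclusive ($|\bar y_i| \ge t$); the adjacency test is strict
  ($> d$).
* **Coordinates.** 1-based inclusive, $d_i = \mathrm{end} -
  \mathrm{start} + 1$; a `length_convention = "half_open"` option
  covers the other SEG dialect found in the wild. All metrics only
  require internal consistency.
* **Chromosomes.** Autosomes 1–22 plus X and Y, in that order;
  segments on other contigs are dropped with a warning on read. Strand
  is meaningless for copy-number segments and ignored.

## Statistical procedures

**Spearman correlation** is the Pearson correlation of mid-ranks
(average ranks on ties), computed via `stats::cor`; unit tests verify
it against an explicit rank-counting oracle. Correlations are reported
without p-values: the analysis interest is in coefficient patterns
across cohorts, not correlation significance.

**Mann–Whitney test.** The statistic counts dominating pairs with ties
half-weighted, so $U + U' = n_a n_b$ under group swap. The two-sided
p-value is exact — twice the smaller tail of the null distribution of
$U$ — when the combined sample size is at most 12 and no ties are
present, and otherwise uses the normal approximation with
tie-corrected variance and a 0.5 continuity correction. The switch
point keeps enumeration where it is trivially cheap and the standard
approximation elsewhere; the exact path is tested against full
enumeration of all label assignments, and when both groups are
identical and constant the test returns p = 1 with a warning rather
than 0/0.

**Multiple testing.** Bonferroni, $\min(1, m\,p)$, with the family
defined as the cohorts tested for one (metric, contrast) pair. This
matches a per-panel "top cohorts" presentation in which each panel is
one metric and one contrast; a `family_size` argument widens the
family (e.g. to cohorts × metrics) for more conservative scoping.
Cohorts where either group falls below `min_group_size` (default 3)
are skipped and listed, not silently dropped. The reported `direction`
is the sign of the group-a minus group-b median difference, which the
significance test alone does not convey.

**Quartiles** in the distribution summaries use linear interpolation
(type 7), the R default.

**Clustering order** comes from `stats::hclust` on
`stats::dist(..., "euclidean")` with complete linkage; the leaf order
is deterministic given the input, which is what the pipeline's
bit-reproducibility guarantee needs.

## The synthetic-cohort generator

The generator emulates the statistical shape of masked SNP-array
copy-number tables: per chromosome, a Poisson number of breakpoints
(rate $\lambda$ per Mb) placed uniformly tiles the chromosome into
contiguous segments; each segment is independently aberrant with
probability $p_{\mathrm{alt}}$; aberrant means are $s \cdot
\max(m_0,\ \mu_a + \sigma_a z)$ with random sign $s$, and neutral
means are $\sigma_n z'$. The truncation floor $m_0$ (default 0.2,
equal to the default threshold) keeps "aberrant in truth" and
"aberrant by threshold" aligned, which is what makes the power results
interpretable as recovery of an injected effect rather than of a
threshold artefact.

Defaults, chosen once as realistic study conditions: $\lambda = 0.05$
/Mb (≈150 breakpoints on the 22-autosome default genome, the order of
segment counts in array-based profiles), $p_{\mathrm{alt}} = 0.1$,
$\mu_a = 0.5$, $\sigma_a = 0.1$, $\sigma_n = 0.05$, and a threefold
tumor effect on $p_{\mathrm{alt}}$. Clinical covariates (T1/T4, N0/N1,
M0/M1, sex) are assigned in balanced random halves per cohort; effects
multiply $p_{\mathrm{alt}}$ (capped at 1) and/or $\mu_a$ for tumor
samples, T4, M1, N1, and — by convention, matching the direction most
often reported for head-and-neck cancer — male patients. One tumor
sample per patient by default; `paired_normal = TRUE` adds a
baseline-burden normal per patient. Sample identifiers follow the
TCGA barcode shape so the default 12-character patient-prefix join is
exercised.

Because segment lengths are independent of aberration status, the
expected FGA has the closed form
$p_{\mathrm{eff}} \Pr(|\text{aberrant mean}| \ge t) +
(1 - p_{\mathrm{eff}}) \Pr(|\sigma_n z| \ge t)$,
implemented in `expected_altered_fraction()` and verified by
simulation within three standard errors in the test suite.

What the generator does *not* model: whole-genome doubling, the
focal-vs-arm-level length structure of real aberrations, clonal
mixtures, probe-level noise, or correlated breakpoint hotspots.
Passing tests therefore demonstrate that the pipeline recovers effects
under an exchangeable segmentation model, not that any metric is well
calibrated on a particular platform's artefacts.

```{r example}
cohort <- simulate_cohort(simulation_config(genome = toy_genome(),
                                            n_per_group = 10,
                                            paired_normal = TRUE,
                                            seed = 1))
scores <- cin_scores(cohort$segments)
scored <- left_join(scores,
                    cohort$truth[, c("sample_id", "cancer_type", "class",
                                     "t_stage", "n_stage", "m_stage",
                                     "sex")],
                    by = "sample_id")
summarize_distributions(scored) |> filter(metric == "fga")
```

## Clinical-table handling

Stage labels collapse to their letter+digit prefix ("T1a" → "T1",
"N0 (i−)" → "N0"); 'X' stages and unparsable labels become missing
(with a warning for the latter), because the contrasts compare pure
T1/T4, M0/M1, N0/N1 groups and sub-stage or unassessable records have
no place in them. The metastasis attribute is selectable per cohort
(`ajcc_pathologic_m` in general, `ajcc_clinical_m` where that is the
recorded attribute, as for adrenocortical carcinoma). Sample types map
to tumor/non-tumor through exact matching against the ten standard
sample-type labels; anything else is `unknown` and excluded from
summaries and tests. Cohorts occurring predominantly in one sex
(CESC, OV, PRAD, TGCT, UCEC, UCS) are excluded from the sex contrast
by default. Patients with several tumor samples contribute each sample
to the clinical tests (the join is per sample); deduplication, where
wanted, is a pre-filter on the scores table.

## Numerical and degenerate-input choices

Empty segment lists are an error for every metric (there is no
meaningful zero); empty *aberrant* sets are not. Validation
(non-overlap, ordering, finite means, recognised chromosomes) is
reported as data rather than raised, and the pipeline either aborts
naming the offending samples or, in skip-invalid mode, drops exactly
those samples so one corrupted cohort cannot contaminate another's
outputs. All pipeline outputs are tab-separated with LF newlines and
UTF-8 encoding; score reals are printed at 6 significant digits;
the manifest records an MD5 per file, and identical configuration plus
seed reproduces identical hashes (the generator consumes its own seed
via a scoped RNG so callers' random streams are untouched).

## Problem sizes in the test suite

The suite exercises the oracle-equivalence checks on 200 random
samples, the Mann–Whitney exact path on every no-tie split up to a
combined n of 10 against full enumeration, type-I control on 1000
null families of 20 cohorts, power on 200 replicate cohorts of 100
samples (threefold aberration-probability effect, toy genome), and
analytic FGA recovery on 500-sample cohorts at three parameter
settings — sizes picked so the whole suite stays fast on a laptop
while the Monte-Carlo margins (three standard errors; a 0.07 bound on
a ~0.05 family-wise rate) remain comfortably informative.

## Known limitations

The scores are single-snapshot, bulk-profile summaries: they cannot
see temporal dynamics or subclonal heterogeneity, and array-like
segment means conflate purity and ploidy with aberration amplitude.
No ploidy correction, allele-specific calling, recurrence analysis, or
per-gene annotation is attempted. The association layer is
deliberately univariate — one metric, one contrast, one cohort at a
time with rank tests — and makes no causal or multivariable claims.
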