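Package: cinscores
Title: Chromosomal Instability Scores from Segmented Copy-Number Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes six per-sample surrogate scores of chromosomal
    instability (total aberration index, modified total aberration index,
    copy number abnormality, break points, altered base segments, and
    fraction of genome altered) from segmented copy-number tables in the
    SEG dialect, compares the scores across samples and cancer cohorts
    with Spearman correlation and complete-linkage clustering, and tests
    their association with tumor stage, metastasis, nodal involvement,
    and patient sex using Mann-Whitney tests with Bonferroni correction.
    Includes a synthetic-cohort generator with analytic expectations so
    the full pipeline is testable without external downloads, and an
    end-to-end runner with deterministic, hashed outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
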