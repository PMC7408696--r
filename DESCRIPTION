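Package: depmarker
Title: Predictive Biomarker Discovery from Gene-Essentiality Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens cancer cell-line panels for gene mutations that predict
    sensitivity to inhibition of a drug target. Knockdown essentiality scores
    (DEMETER-like, more negative = more essential) are tested for differential
    essentiality between mutant and wild-type lines with a moderated t-test
    using empirical-Bayes variance shrinkage, and the resulting p-values are
    corrected by a grouped (per-biomarker) local false discovery rate.
    Includes cohort-level target pre-filters (essentiality prevalence,
    cohort specificity, expression), drug-target mapping, mutation
    co-occurrence checks, k-nearest-neighbour imputation of missing scores,
    and a fully synthetic data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
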