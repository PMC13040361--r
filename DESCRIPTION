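Package: cinscore
Title: Chromosomal Instability Scoring from Low-Coverage Whole-Genome
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-depth copy-number analysis of low-coverage whole-genome
    sequencing for tumor prognostics. Bins aligned reads into fixed-width
    genomic windows, standardizes per-bin coverage against a healthy-control
    panel (Z-scores), segments the Z-profile with an in-house circular binary
    segmentation implementation, and summarizes genome-wide copy-number burden
    as a chromosomal instability (CIN) score together with chromosome-arm
    Z-scores. Includes survival-oriented tooling for relating the score to
    recurrence: maximally selected rank statistics for cutoff selection,
    Kaplan-Meier/log-rank and Cox proportional-hazards wrappers, IPCW
    time-dependent ROC, Harrell's C, likelihood-ratio and net-reclassification
    comparisons, plus a synthetic-cohort generator so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    broom,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
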