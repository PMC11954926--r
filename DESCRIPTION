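Package: abexp
Title: Tissue-Specific Prediction of Aberrant Gene Underexpression from Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the AbExp approach for predicting aberrant gene
    underexpression across tissues from an individual's rare genetic variants.
    Builds labeled expression-outlier benchmarks from negative-binomial outlier
    caller results (OUTRIDER-style tables), engineers gene-level features by
    weighting variant consequences with tissue-specific isoform proportions,
    trains gradient-boosted-tree z-score regressors with individual-grouped
    cross-validation, integrates RNA-seq evidence from clinically accessible
    tissues via an interaction logistic model, and provides precision-recall
    evaluation, enrichment statistics, rare-variant association testing, and a
    self-contained synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    xgboost,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
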