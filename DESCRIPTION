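Package: radsens
Title: Rank-Based Radiosensitivity Index Scoring and Immune Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the rank-based ten-gene radiosensitivity index (RSI)
    per tumour sample, stratifies cohorts at a published cut-off, scores
    single-sample T-cell-inflamed enrichment with a kernel-CDF weighted
    Kolmogorov-Smirnov statistic, relates RSI to macrophage polarisation and
    immune covariates, classifies the IFN-gamma-dominant (C2) immune subtype
    with random-forest Gini importance, and stratifies survival by optimal
    cut-points. Ships a synthetic-cohort generator that emulates the
    statistical structure of bulk expression cohorts with immune fractions
    and survival outcomes, so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
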