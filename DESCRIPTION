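Package: clockshift
Title: Dataset-Shift Diagnostics and Uncertainty-Aware Epigenetic Aging Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether an epigenetic aging clock can be
    trusted on a new cohort. Implements covariate-shift diagnostics for
    methylation beta-value matrices (per-CpG two-sample Kolmogorov-Smirnov
    tests with Benjamini-Hochberg correction and PCA embeddings), sparse
    penalized aging clocks with cross-validation, the Inverse Train-Test
    Procedure for dataset interchangeability, a Gaussian-process aging clock
    whose posterior variance quantifies out-of-distribution uncertainty, and
    variance-aware group significance tests (z-test, REML meta-regression,
    Mann-Whitney). Ships a synthetic-data module emulating aging,
    reprogramming, and anthropometric cohorts so the whole framework is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    caret,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
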