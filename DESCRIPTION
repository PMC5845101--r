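Package: ehrmiss
Title: Missingness Characterization and Imputation Benchmarking for
    Electronic Health Record Laboratory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Clinical laboratory results in electronic health records are
    mostly missing, and the mechanism of missingness (MCAR, MAR, MNAR)
    determines which imputation strategies are defensible. 'ehrmiss'
    provides an end-to-end framework for studying this problem: a
    synthetic EHR-like data generator with known correlation structure and
    configurable missingness mechanisms, preprocessing of long-format lab
    events into Box-Cox and Z-transformed patient-by-variable matrices,
    missingness diagnostics (completeness ranking curves and random-forest
    prediction of value presence), construction of representative
    complete-case benchmark sets by covariate matching, amputation of
    complete data under four mechanisms (MCAR, MAR, MNAR, and realistic
    pattern copying), native implementations of eleven imputation methods
    including multiple imputation by chained equations with predictive
    mean matching, and evaluation by masked-cell RMSE and
    multiple-imputation calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
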