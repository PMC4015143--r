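Package: dnamclock
Title: Multi-Tissue DNA Methylation Age Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Train, evaluate and apply elastic-net DNA methylation age
    ("epigenetic clock") predictors on CpG beta-value matrices. Implements
    the piecewise log-linear age calibration transform and its inverse,
    penalized-regression clock fitting with cross-validated penalty
    selection, clock shrinkage along the penalty path, gold-standard
    quantile normalization and mean imputation for test arrays, age
    acceleration statistics, twin-based Falconer heritability,
    leave-one-data-set-out cross-validation, biweight midcorrelation,
    Stouffer meta-analysis of within-data-set age correlations,
    tissue-effect F statistics, annotation-category enrichment tests, and a
    calibrated synthetic methylome generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
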