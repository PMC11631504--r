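Package: penGrids
Title: Penalized Regression Lambda Grids and Nested Cross-Validation for
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction with penalized (ridge, lasso, elastic-net)
    regression, featuring two strategies for constructing the candidate
    regularization-parameter grid: the conventional glmnet-style
    regularization path and a variance-component-ratio grid that maps
    log-spaced proportions of explained phenotypic variance to penalty
    values. Includes nested k-fold cross-validation for tuning and
    evaluation, a spectral-REML GBLUP comparator built on the VanRaden
    genomic relationship matrix, and a quantitative-trait simulator with
    controlled heritability so every pipeline stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
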