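Package: wavesurv
Title: Supervised Wavelet Dimension Reduction for Survival Prediction
    from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts right-censored patient survival from high-dimensional
    gene-expression matrices by combining a univariate Cox proportional-hazards
    screen with level-1 discrete Haar wavelet feature extraction, and fitting a
    multivariate Cox model on the resulting approximation coefficients. Includes
    two reference reducers sharing the same train/apply contract (supervised
    principal components with a cumulative-variance rule, and sequential
    partial-least-squares Cox components), five evaluation criteria (Nagelkerke
    R-squared, Gonen-Heller concordance probability, Harrell C-index, likelihood
    ratio statistic, and the IPCW integrated Brier score), a block-structured
    simulation generator for benchmarking, and a repeated train/test split
    evaluation harness with paired method comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
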