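Package: boxcoxopt
Title: Classifier-Dependent Optimization of Multivariate Box-Cox
    Transformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Preprocessing tool that tunes one Box-Cox power-transformation
    exponent per feature column to maximize the accuracy of a downstream
    classifier, rather than the Gaussianity of the data.  Provides the
    multivariate Box-Cox transform with the bracketing scalers (range
    standardization to [1,2] and zero-mean/unit-variance scaling), five
    lambda-selection strategies (column-wise maximum likelihood, spherical,
    diagonal, exhaustive two-dimensional grid search, and an iterative
    coordinate grid search with restart, direction-shuffling and local
    grid-refinement variants), a train/predict pipeline, a repeated
    stratified cross-validation harness, two-dimensional accuracy-heatmap
    exploration with optimum annotation, synthetic binary dataset
    generators, chi-square feature ranking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    RcppArmadillo,
    Rcpp
Suggests:
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
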