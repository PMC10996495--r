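Package: poispca
Title: Poisson GLM-PCA for Sparse Count Matrices by Alternating Poisson Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Dimensionality reduction of sparse count matrices (for example
    single-cell RNA-seq gene-by-cell counts) under the Poisson GLM-PCA model,
    in which each count is Poisson with a log-scale mean given by a low-rank
    matrix plus optional gene- and cell-level covariate terms.  Models are fit
    by alternating Poisson regression: block-coordinate alternation between
    independent cell-wise and gene-wise Poisson generalized linear models, each
    solved by cyclic coordinate descent with safeguarded one-dimensional Newton
    updates, so the log-likelihood is monotonically non-decreasing.  Factors
    are orthogonalized every iteration, yielding a PCA-like decomposition with
    orthonormal loadings and sorted scales.  All computations respect the
    sparsity of the data: no dense matrix the size of the count matrix is ever
    formed.  Includes a generator for synthetic single-cell-like counts with
    known ground truth, broom-style tidiers, ggplot2 plotting, and a two-phase
    (init, fit) command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
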