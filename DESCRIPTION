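Package: srclatlrr
Title: Tumor Classification by Sparse Representation over Latent Low-Rank Salient Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gene-expression samples (genes x samples, m >> n) by
    decomposing the training matrix X into principal features XZ, salient
    features LX, and sparse noise E via latent low-rank representation
    (nuclear-norm minimization solved with an inexact augmented Lagrange
    multiplier scheme), then sparse-coding projected test samples over the
    salient-feature dictionary D = LX with an l1-regularized least-squares
    solver and assigning the class of minimum reconstruction residual.
    Includes between-to-within sums-of-squares (BW) gene selection,
    stratified k-fold cross-validation, a lambda-sweep diagnostic relating
    classification accuracy to the amount of noise removed, and generators
    for expression-like synthetic data on unions of low-dimensional
    subspaces with dense noise and sparse gross corruption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
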