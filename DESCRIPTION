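Package: biconn
Title: Bilinear Modeling of Neuronal Type Connectivity from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a bilinear latent-factor model that maps pre- and
    post-synaptic gene-expression profiles to a synaptic connectivity
    matrix, in the spirit of collaborative-filtering recommendation
    systems. Connectivity between a presynaptic and a postsynaptic
    neuron (or neuronal type) is modeled as the inner product of their
    linearly transformed expression features, z = (xA)(yB)', and the
    transformation matrices are estimated by alternating gradient
    descent with L2 or Gram-matrix regularization. The package also
    provides the spatial connectome model (rule-matrix ridge
    regression) as a baseline, a discrepancy-score comparison of rule
    matrices, single-cell count preprocessing (median normalization,
    highly variable gene selection, PCA, type-wise statistics),
    connectivity-matrix construction from stratification profiles or
    contact-masked adjacency, cross-validation over the regularization
    strength and latent dimension, ROC/correlation evaluation,
    run-to-run consistency scoring, latent-space interpretation
    (per-dimension reconstruction, gene-weight back-projection, partner
    prediction), and seeded synthetic-data generators with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Matrix,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
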