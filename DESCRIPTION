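Package: vadeclust
Title: Variational Deep Embedded Clustering of Single-Cell RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters single-cell RNA-seq expression profiles with a
    variational autoencoder whose latent space is modelled by a
    diagonal-covariance Gaussian mixture trained under a joint variational
    objective (VaDE-style deep clustering). Includes count-matrix readers
    for 10x MTX and dense CSV/TSV, quality-control filtering and
    normalization, a group-structured negative-binomial count simulator
    with additive-noise and dropout-corruption layers, external clustering
    metrics (adjusted Rand index, normalized mutual information,
    classification metrics), and benchmarking utilities (PCA baseline,
    k-means, t-SNE export, latent-versus-raw feature classification,
    corruption robustness curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    e1071,
    randomForest,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
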