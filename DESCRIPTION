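Package: spotfuse
Title: Spatial Domain Detection from Spot-Level Expression and Image Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects discrete spatial domains in a single spatially resolved
    transcriptomics tissue section (10x Visium style) by fusing spot-level gene
    expression with image-derived protein or histology features. Spot features
    from each modality are passed through a graph convolutional autoencoder over
    the k-nearest-neighbour spot graph and refined with Deep-Graph-Infomax style
    contrastive self-supervised learning; top principal components of the
    reconstructed modalities are concatenated into a hybrid profile, clustered
    with a model-based Gaussian mixture (mclust), and spatially refined. Includes
    readers for Visium-style directories (MatrixMarket counts, tissue positions,
    scale factors, multi-channel TIFF), a convolutional autoencoder for per-spot
    image patches, a synthetic Visium-like data generator with known ground-truth
    domains, and evaluation utilities (Adjusted Rand Index, silhouette).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    cluster,
    jsonlite,
    mclust,
    methods,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
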