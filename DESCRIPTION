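Package: arborcode
Title: Potential-Connectivity Cell Typing of Single-Neuron Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-brain potential-connectivity ("c-type") analysis of
    atlas-registered single-neuron reconstructions. Reads and resamples SWC
    morphologies, detects arbor domains per soma-location type by Gaussian
    mixture clustering with BIC model selection and encloses them in 3-D
    alpha-shapes, computes per-neuron axon-to-dendritic-domain overlap
    connectivity barcodes, scores cluster separability with an exponential
    Manhattan-distance similarity (m-score / c-score), measures anatomy-aware
    soma distances with a region-covariance Mahalanobis metric, and derives
    spatially tuned connectivity subtypes by distance-weighted hierarchical
    clustering with Calinski-Harabasz model selection. Includes a synthetic
    mirrored-hemisphere atlas and morphology generator so the whole pipeline
    is testable without any proprietary dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mclust,
    e1071,
    jsonlite,
    yaml,
    digest,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
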