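Package: spatopic
Title: Spatially Aware Bayesian Topic Models for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable topic modeling of spatial transcriptomics count
    data. Decomposes a cell-by-gene count matrix into per-cell topic
    proportions and sparse per-topic gene modules under a Gamma-Poisson
    (negative binomial) likelihood with a structured regularized horseshoe
    prior on module scores. Spatial coordinates enter through a simplified
    graph-convolution encoder used for amortized stochastic variational
    inference. Extensions handle multi-sample batch effects (Student-t /
    Beta outer-product terms) and time-series gene modules (Matern-3/2
    Gaussian process drift). Includes synthetic-data generators for
    overlapping spatial patterns, topic-quality metrics (NPMI module
    coherence, rank-biased-overlap module diversity, Moran's I), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    clue,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
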