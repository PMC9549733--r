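Package: cellmotility
Title: Single-Cell Motility Feature Extraction, State-Space Clustering and
    3D Drift Correction for Time-Lapse Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-cell migration from time-lapse tracking
    tables. Computes a per-track battery of motility statistics (path and
    speed metrics, mean-squared-displacement power-law slope, rescaled-range
    Hurst exponent, non-Gaussian displacement parameter, random-walk baseline
    deltas, movement occupancy and displacement autocorrelation), builds a
    motility state space by PCA and Ward hierarchical clustering with
    silhouette scoring and t-SNE visualisation, tests condition-by-cluster
    proportions with the chi-squared test, and corrects rigid drift of 3D
    tissue constructs from fiducial tracks selected by cosine similarity of
    their displacement series. A seeded synthetic trajectory generator
    (Brownian, persistent random walk, directed, Levy, and per-condition
    mixtures) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    igraph,
    Rtsne,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
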