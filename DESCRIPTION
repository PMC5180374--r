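Package: spinetax
Title: Dendritic Spine Shape Taxonomy and Shape-Transition Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Unsupervised construction of dendritic spine shape taxonomies
    from per-spine morphometric descriptor tables measured at two time
    points, and probabilistic modelling of shape transitions between the
    resulting clusters. Provides balanced subpopulation selection by greedy
    closest-pair matching, split principal component analysis yielding
    interpretable size and contour features, crisp (average-linkage
    hierarchical) and fuzzy c-means shape clustering with knee-point model
    selection on within-cluster sum of squares, estimation of row-stochastic
    shape-transition matrices by constrained quadratic programming, bootstrap
    standard errors for transition probabilities, and bootstrap hypothesis
    tests comparing two populations through relative-distribution-change
    (RDC) and squared-matrix-difference (SMD) statistics. Includes a
    synthetic spine-population generator with known ground truth for
    validation, cross-validated prediction-error comparisons against
    baseline models, and transition-graph export in DOT format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
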