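Package: morphodyn
Title: Morphodynamic Quantification of Sessile Cells in Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Morphodyn", "Developers", email = "morphodyn@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for quantifying the morphodynamics of
    sessile cells (e.g. resident tissue macrophages) in 2D time-lapse
    microscopy. Provides seeded watershed segmentation and labeling of
    probability-map movies, 31 human-interpretable per-cell size, shape
    and dynamics quantifiers (including fixed/mobile area, Sholl-style
    protrusiveness and dynamic area change), and population-level
    statistics: permutation Welch tests, an exact Rosenbaum cross-match
    test for multivariate two-sample comparison, and a PCA morphospace.
    Includes a ground-truthed synthetic-movie generator so every stage
    is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
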