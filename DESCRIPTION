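Package: topoinfo
Title: Topological and Information-Theoretic Analysis of Higher-Order Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to compare topological and information-theoretic notions of
    higher-order structure in multivariate data. Implements k-nearest-neighbor
    estimators of total correlation, dual total correlation, O-information and
    S-information from a single joint-space neighbor search; generators for
    benchmark point clouds with known topology (lines, planes, spheres, balls,
    tori and torus knots); Vietoris-Rips persistent homology up to dimension 2
    on Chebyshev distance matrices with void-count and persistence summaries;
    a synthetic multi-scan BOLD-like time-series generator with planted
    redundant and synergistic triads; and a circular-shift surrogate screen
    that classifies triads of channels as redundancy- or synergy-dominated.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
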