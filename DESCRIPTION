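Package: lineagegrid
Title: Spatial Stochastic Models of Feedback and Feedforward Regulation in
    Cell Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid stochastic-deterministic simulation of cell-lineage
    regulation on a two-dimensional lattice. Stem, transit-amplifying and
    differentiated cells divide, differentiate, die and migrate on an n x n
    grid, coupled to deterministic per-patch reaction-diffusion dynamics of
    diffusible signalling mediators: a negative-feedback factor secreted by
    differentiated cells that suppresses stem-cell self-renewal, and a
    feedforward factor secreted by stem cells that maintains the
    transit-amplifying compartment. Includes the corresponding mean-field
    ordinary differential equation models with closed-form and numerical
    equilibria, quadrat-based index-of-dispersion statistics for classifying
    spatial outcomes (extinct, uniform, clumped), scenario presets, replicate
    orchestration, and two-parameter log-uniform sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    deSolve,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
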