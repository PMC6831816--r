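Package: zippersim
Title: Kinetic Simulation of Competing Parallel and Antiparallel Amyloid
    Nanocrystal Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven stochastic (Gillespie) simulation of hierarchical
    self-assembly of amyloid-forming peptides into rectangular nanocrystals,
    resolving the competition between a parallel (herringbone, p2) and an
    antiparallel (rectangular, p1) beta-sheet polymorph. Provides anisotropic
    steric-zipper interface free-energy models, estimators that recover
    per-interface standard energies from block free-energy tables, rod-like
    particle translational diffusion coefficients, collision and fragmentation
    rate kernels including compound collision-with-split reactions, and
    polymorph-resolved observables (mass fractions by aggregate
    dimensionality, cross-sectional aspect ratios, crossover-concentration
    extraction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
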