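Package: foldscape
Title: Collective-Variable Discovery and Free-Energy Landscape Analysis
    for Early Protein Misfolding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the early misfolding of helical proteins
    at desk scale: supervised construction of a one-dimensional collective
    variable by harmonic linear discriminant analysis (HLDA) from
    inter-helix descriptors (per-helix alpha-helical content and
    switching-transformed helix centre-of-mass distances), well-tempered
    metadynamics with parallel tempering on analytic toy potentials,
    free-energy-surface estimation and convergence diagnostics,
    minimum-energy (minimax) path extraction over FES grids with barrier
    reporting in RT, and per-basin structural characterisation (helicity,
    secondary-structure populations, radius of gyration, helix distance
    matrices, and solvent-accessible surface area of aggregation-prone
    regions). Synthetic generators provide labelled descriptor ensembles,
    ideal and partially melted helical backbones, Langevin trajectories on
    analytic potentials, and free-energy grids with planted features, so
    the whole pipeline is exercised end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
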