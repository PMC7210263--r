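Package: rxnforge
Title: Automated Elementary-Reaction Dataset Generation and Curation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building curated datasets of gas-phase elementary
    reactions over H, C, N and O from automated potential-energy-surface
    exploration. Implements exhaustive driving-coordinate enumeration from a
    reactant connectivity graph under valence and symmetry constraints,
    parsing of geometry-optimization + harmonic-frequency records and
    string-path outputs, normal-mode verification of proposed transition
    states, perception of atom-mapped reaction SMILES from 3D geometries,
    zero-point-corrected activation energies and reaction enthalpies,
    duplicate handling, dataset assembly in a standard CSV + per-reaction
    directory layout, and diversity analyses (bond-change statistics,
    reaction-template extraction, kernel density estimates). The external
    quantum-chemistry and path-optimization engine is a pluggable executor
    contract; a seeded mock executor and fixture generators make the full
    pipeline testable without any quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
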