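Package: magicratio
Title: Phase Separation of Two-Component Sticker-Spacer Associative Polymers
Version: 0.1.0
Authors@R: person("Magic", "Ratio", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying liquid-liquid phase separation of two-component
    multivalent associative polymers that bind one-to-one. Provides a
    coarse-grained Langevin simulator of sticker-spacer bead chains with
    cross-type attraction and same-type repulsion, trajectory analysis
    (bond detection, cluster composition, slab density profiles, coexistence
    concentrations), an analytical dimer-gel mean-field free energy with an
    association-state solver, convex-hull construction of two-component phase
    diagrams with tie lines, and synthetic planted fixtures for testing the
    full analysis chain. Demonstrates the magic-ratio effect: suppression of
    phase separation at rational polymer stoichiometries under strong binding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
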