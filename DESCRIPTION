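Package: eaesim
Title: Agent-Based Simulation of CD8 Regulatory T Cell Control in Murine EAE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale agent-based simulator of the regulatory T-cell
    circuit that terminates autoimmune episodes in murine experimental
    autoimmune encephalomyelitis (EAE): dendritic cells efferocytose apoptotic
    encephalitogenic CD4Th1 cells, present TCR-derived peptides, are licensed
    by CD4Treg cells to express Qa-1, cross-prime cytotoxic CD8Treg cells, and
    the resulting CTLs selectively kill CD4Th1 cells. The package provides the
    simulation engine (compiled core with reproducible seeded ensembles), a
    registry of in silico experiments (mutually exclusive peptide
    presentation, constitutive Qa-1 expression delays with CD4Treg
    abrogation, relaxed CD8Treg grid occupancy), calibration utilities, and a
    Vargha-Delaney A-test analysis layer for effect-magnitude comparison of
    simulation ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
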