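Package: qmdff
Title: Quantum-Mechanically Derived Force Fields and Non-Equilibrium
    Solvation Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for building state-specific classical
    force fields from quantum-mechanical descriptors (Hessians, relaxed
    torsional scans, per-state atomic charges), mimicking vertical
    photoexcitation by switching a chromophore's force field between
    electronic states inside a swarm of non-equilibrium molecular-dynamics
    trajectories, and quantifying the subsequent solvent-shell
    reorganization through time-windowed radial distribution functions and
    ensemble-averaged absorption spectra.  A synthetic "mock QM" backend
    with analytically defined teacher potentials replaces electronic
    structure calculations so that every stage of the pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    pracma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
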