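Package: stericzipper
Title: Steric-Zipper Nanocrystal Construction, Scattering Prediction, and
    Interface Thermodynamics for Amyloid Hexapeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying parallel versus antiparallel
    amyloid steric-zipper assembly. Builds idealized beta-strand hexapeptides
    and replicates them into nanocrystal blocks obeying any of the eight
    steric-zipper symmetry classes; predicts orientationally averaged solution
    X-ray scattering from explicit coordinates via the Debye equation with
    excluded-volume solvent contrast; detects backbone hydrogen bonds and
    classifies strand pairings as parallel or antiparallel over trajectories;
    provides a coarse-grained peptide energy model with screened
    electrostatics, a Hamiltonian replica-exchange engine with a harmonic
    reference restraint, and a block-cutting interface free-energy
    decomposition producing sheet-elongation and zipper-formation free
    energies and their parallel-minus-antiparallel differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
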