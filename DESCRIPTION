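Package: fepnet
Title: Alchemical Free-Energy Perturbation Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis layer for relative binding free-energy calculations on
    congeneric ligand series. Estimates per-leg free energies from reduced
    potential samples with the multistate Bennett acceptance ratio (MBAR)
    estimator, assembles relative binding free energies over a perturbation
    network, reconstructs absolute binding free energies against a reference
    ligand by weighted least squares, handles racemic ligands by Boltzmann
    combination of enantiomer results, computes hysteresis and thermodynamic
    cycle-closure diagnostics with threshold flagging, and benchmarks
    predictions against experimental inhibition constants with bootstrap
    uncertainties. Includes a synthetic-data generator with exactly solvable
    Gaussian states for end-to-end validation against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    MASS,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
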