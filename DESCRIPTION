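Package: pkasim
Title: Stochastic-Titration Constant-pH Simulation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discrete constant-pH molecular simulation at the
    desk scale: derivation of continuum-electrostatics atomic radii from
    Lennard-Jones parameters via a 2 RT water-interaction criterion, a
    finite-difference linear Poisson-Boltzmann solver with two-step grid
    focusing, intrinsic pKa and site-site interaction energies for
    titratable groups, Metropolis Monte Carlo sampling of
    protonation/tautomer microstates (with an exact enumerator for small
    systems), Hill-equation titration analysis with jackknife errors,
    isoelectric points, model-compound pKa calibration, pH-dependent
    counterion estimation, and pKa-prediction benchmarking against
    experimental values including a null (reference-pKa) model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
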