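Package: fibrilhydro
Title: Hydrodynamic Length-Distribution Analysis of Cylinder-Like Amyloid
    Fibrils from Sedimentation Velocity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links analytical-ultracentrifugation (AUC) sedimentation
    coefficients of fragmented, cylinder-like amyloid fibrils (such as those
    formed by beta-lactoglobulin) to their length and height through rigid-rod
    hydrodynamics. Provides the forward and inverse cylinder model based on the
    equivalent-sphere frictional ratio, machinery for number-, mass- and
    extinction-weighted size distributions and their interconversion between
    length space and sedimentation-coefficient space, a Brownian-dynamics
    simulator of constant-speed gravitational-sweep experiments, a
    two-dimensional length-by-height broadening analysis, and power-law fitting
    of comminution (size-reduction) kinetics under rotor-stator stressing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
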