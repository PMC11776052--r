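Package: porecv
Title: Collective Variables and Free-Energy Tools for Membrane Pore Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study pore nucleation and expansion in lipid membranes
    with path-like collective variables. Implements a joint "Full-Path"
    collective variable that blends a cylinder-density defect coordinate with
    a soft-minimum pore-radius coordinate (with exact analytic per-particle
    gradients), and a "Rapid" box-length collective variable that estimates
    membrane edge line tension from lipid-stripe simulations. Supporting
    machinery includes seeded generators of membrane-like bead configurations
    (flat bilayers, bilayers with cylindrical pores and a water column, lipid
    stripes with two rims), a minimal implicit-solvent bead-lipid Langevin
    engine for biased sampling, umbrella-sampling window layout, a weighted
    histogram analysis method (WHAM) solver with halves and bootstrap error
    estimates, quadratic (nucleation coefficient) and linear (line tension)
    free-energy fits, and a slice-occupancy pore-state observable with
    hyperbolic-tangent pore-lifetime fitting. Readers and writers for GRO,
    XYZ and COLVAR-style time-series files are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    graphics,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
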