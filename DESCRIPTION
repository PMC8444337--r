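Package: cectrack
Title: Center-of-Excess-Charge Tracking and Biasing for Proton Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks the excess-proton charge defect in molecular dynamics
    trajectories through a center-of-excess-charge (CEC) collective variable
    built from diabatic proton-hop states. Enumerates bonding topologies
    reachable by Grotthuss hops through three solvation shells of the
    hydrogen-bond network, weights them with an exponential charge-transfer
    model, and returns the CEC position, per-atom excess charges, the
    excess-charge dipole and analytic gradients. Downstream tools compute the
    excess-charge infrared spectrum from the CEC velocity autocorrelation
    function, a smooth proton-dissociation coordinate with gradients for
    enhanced sampling, a well-tempered metadynamics accumulator with a toy
    Langevin demonstration, and least-squares calibration of the exponential
    charge-transfer parameters from gas-phase training grids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
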