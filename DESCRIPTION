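Package: pomsim
Title: Stochastic and Semi-Analytical Models of Flux-Based PomXY Cluster
    Positioning on the Bacterial Nucleoid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven (Gillespie) lattice-gas simulation of ParA/MinD-family
    ATPase (PomZ) dimers that tether the PomXY cargo cluster to a one-dimensional
    nucleoid in Myxococcus xanthus, together with the stationary
    reaction-diffusion model of the PomZ density and flux, and a semi-analytical
    theory that predicts the average cluster trajectory from the flux difference
    into the cluster, the single-dimer force constant and the effective friction
    coefficient of the cluster. Includes the estimators used to analyse
    trajectories: ensemble binning, position-conditioned density and flux
    profiles, flux-difference and force-velocity fits, and oscillation detection
    by FFT peak finding and histogram bimodality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
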