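Package: thromboflow
Title: Boundary-Integral Simulation of Platelet-Thrombus-Erythrocyte
    Hydrodynamics in a Periodic Arteriole
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of cellular blood flow past a
    mural thrombus in a streamwise-periodic cylindrical arteriole.  Implements
    a triply periodic boundary-integral Stokes solver (Ewald-split Stokeslet),
    spherical-harmonic elastic red-blood-cell membranes with Skalak in-plane
    and Helfrich bending resistance, a rigid oblate-spheroid platelet with
    force- and torque-free dynamics, a parametric Gaussian thrombus bump, and
    the full set of stenotic-flow statistics: dimensionless peak velocity
    versus percent area stenosis, near-wall velocity and shear profiles,
    platelet trajectory density and reversibility, deposition-potential maps,
    and flipping statistics.  Synthetic fixtures (analytic toy flows and
    trajectory bundles) make every analysis stage testable without the solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
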