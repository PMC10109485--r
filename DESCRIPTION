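Package: moxiopt
Title: Bioheat Simulation and Interval Uncertainty Optimization for Mild Moxibustion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the thermal dose delivered by mild moxibustion (a burning
    moxa stick suspended above the skin) with an axisymmetric multilayer Pennes
    bioheat solver driven by a radiating disk source, and optimizes the
    operating parameters under interval uncertainty.  Provides Latin hypercube
    design of experiments, a Gaussian radial-basis-function network surrogate
    for the two efficacy indicators (skin surface temperature and thermal
    penetration at 5 mm depth), interval propagation of parameter uncertainty,
    and a nested genetic-algorithm solver for the nonlinear interval program
    constrained by the reliability-based possibility degree of interval (RPDI),
    which keeps skin surface temperature below the 45.5 degree Celsius comfort
    threshold while maximizing thermal penetration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lhs,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
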