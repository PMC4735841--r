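Package: comptwin
Title: Digital Twin of a Three-Layer LaBr3 Compton Telescope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital twin of a three-layer LaBr3 Compton telescope
    for emission imaging, as used in hadron-therapy treatment-monitoring research.
    Provides Klein-Nishina Compton kinematics and photon transport through the
    layered scintillator stack, a Monte Carlo simulator of Na-22 point-source
    measurements with parametric detector response (energy and position blur,
    thresholds, triple-coincidence trigger with accidental and pile-up modelling),
    gamma-spectroscopy calibration utilities (photopeak fitting, linear energy
    calibration, temperature-gain correction, channel equalization),
    three-interaction Compton cone building with incident-energy determination,
    and list-mode ML-EM image reconstruction with resolution and efficiency
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    Matrix,
    minpack.lm,
    generics,
    yaml,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
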