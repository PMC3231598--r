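Package: etongue
Title: Potentiometric Electronic-Tongue Simulation, Characterisation and
    Neural-Network Calibration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying multicomponent mixture resolution with
    cross-sensitive ion-selective electrode arrays ("electronic tongues").
    Simulates the potentiometric response of an electrode panel to sulfide
    and perchlorate mixtures through the Nikolsky-Eisenmann law with
    Debye-Hueckel/Davies activity corrections, generates standard-addition
    experiment tables by exact mass balance, estimates IUPAC performance
    characteristics (slope, detection limit, potentiometric selectivity
    coefficients, reproducibility), trains a Bayesian-regularised
    Levenberg-Marquardt multilayer perceptron that inverts the array
    response to the two ion concentrations, and evaluates mixture
    resolution against single-electrode interpolation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
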