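Package: adsorbkit
Title: Characterization of Porous Adsorbents for Extracorporeal Cytokine Removal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative characterization of porous polymer
    adsorbents used in extracorporeal blood purification. Implements inverse
    size-exclusion chromatography (iSEC) analysis: SEC distribution
    coefficients from retention volumes, power-law Stokes-radius calibration
    of polystyrene standards, accessible pore-size bracketing at a
    configurable distribution-coefficient threshold, intraparticle porosity
    and pore volume. Also provides removal-rate analysis for recirculating
    scale-down adsorption experiments with left-censored detection limits, a
    single-compartment depletion-kinetics fit, dose-response activation
    threshold bracketing for endothelial activation markers, and seeded
    synthetic-data generators (partitioning chromatograms, reservoir
    depletion, sigmoid dose-response) so every analysis stage can be
    exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
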