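Package: extravasim
Title: Gravity-Method Radiopharmaceutical Infusion Modelling and
    Extravasation Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical model of a gravity-method 177Lu-DOTATATE (Lutathera)
    infusion: constant-volume dilution of the vial activity, laminar Poiseuille
    advection of the activity concentration through the infusion line and the
    forearm vein, accumulation of activity and volume at the injection site
    after an extravasation onset, and conversion of the simulated activity
    distributions into an equivalent dose rate (EDR) 1 cm from the injection
    site through a calibrated point-source response. Bedside EDR readings can
    be inverted in real time into estimates of extravasated activity, volume
    and activity concentration, iso-EDR characterization charts (abacuses) can
    be tabulated, and monitoring series can be screened against an empirical
    extravasation alarm threshold.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
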