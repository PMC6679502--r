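Package: lodlamp
Title: Digital Twin of a Lab-on-a-Disc Colorimetric LAMP Instrument
Version: 0.1.0
Authors@R:
    person("lodlamp", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator of a centrifugal lab-on-a-disc instrument
    for loop-mediated isothermal amplification (LAMP) with colorimetric
    endpoint detection. Provides a lumped-capacitance thermal model of a
    laser-heated amplification chamber, a thermochromic sheet (TOCS)
    intensity sensor with heating/cooling hysteresis, an auto-calibrated
    proportional-derivative controller of the laser PWM duty ratio, a
    validated disc driving protocol state machine, a synthetic generator of
    hydroxy naphthol blue (HNB) reaction images, and a colour-feature
    logistic classifier for positive/negative endpoint calling. All inputs
    are simulated; runs are fully seeded and reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
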