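Package: cowbw
Title: Body Weight Prediction for Dairy Cows from Body Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the body weight of dairy cows (Fleckvieh and its Red
    Holstein crosses, Holstein-Friesian, Brown Swiss) from body size
    measurements recorded during routine performance testing, across both
    the lactation and the dry period. Ships published prediction equations
    built on heart girth, belly girth and hip width, with genotype-specific
    regression slopes, parity effects and fitted physiological-stage
    curves; re-estimates such equations from weighing records via a linear
    mixed model with a random herd effect (REML), stage least-squares means
    and polynomial stage curves; and validates predictions by decomposing
    the mean square prediction error into error of central tendency, error
    due to regression and error due to disturbance, together with the
    centered-residual regression. A seeded synthetic-herd generator with
    period-specific correlated measurement profiles makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    MASS,
    Matrix,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
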