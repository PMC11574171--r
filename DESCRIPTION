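Package: bipr
Title: Blink-Induced Pupillary Response Analysis and Twin Heritability
Version: 0.1.0
Authors@R:
    person("Pupillometry", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Preprocessing of continuous eye-tracking pupil recordings
    (blink detection, cubic-spline blink interpolation, zero-phase FIR
    band-pass filtering, downsampling), vigilance-state classification by
    pupil-loss fraction, extraction of blink-locked pupillary response
    profiles and their dilation/constriction peak parameters, test-retest
    reliability via ICC(2,k), paired vigilance-state comparisons, and
    classical twin-study variance decomposition (ACE/ADE structural
    equation models fitted by maximum likelihood with nested chi-square
    path dropping, AIC model selection and profile-likelihood confidence
    intervals). Includes a synthetic-data generator for pupil runs,
    reliability designs and twin cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
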