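Package: sirlic
Title: Signal-Intensity-Ratio Estimation of Liver Iron Concentration from MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating and evaluating signal-intensity-ratio (SIR)
    methods that estimate liver iron concentration (LIC) from 1.5 T spin-echo
    MRI, using paraspinal muscle as the reference tissue.  Includes a
    longitudinal iron-loading cohort simulator (spin-echo and multi-echo
    gradient-echo signal models with Rician noise), ROI summary statistics with
    background censoring, mono-exponential R2* fitting with tail-echo
    truncation, Passing-Bablok regression with rank-based confidence intervals
    and the Cusum linearity test, log-linear and exponential calibration curves
    with measuring-range computation, repetition-time (TR) adjustment and
    calibration-transfer correction, Bland-Altman method agreement, and
    heteroscedastic linear mixed-effects modeling for acquisition-parameter
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
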