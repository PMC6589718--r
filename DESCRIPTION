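Package: noxithresh
Title: Simulation and Analysis of Adaptive Staircase Thresholds for Changes in Noxious Heat
Version: 0.1.0
Authors@R:
    person("Nox", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating two-interval forced-choice (2IFC) detection and
    discrimination of increases and decreases in noxious heat, driven by a
    transformed up-down (3-down/1-up) adaptive staircase. Provides trapezoidal
    temperature stimulus profiles, a signal-detection observer with a
    Stevens-type power-law transducer (linear or positively accelerating),
    staircase engines and threshold estimators, drivers for four experiment
    designs on synthetic cohorts (including an intensity-rating task), and
    first-principles inferential statistics (paired t, 2x2 within-subject
    ANOVA, noncentral-t power analysis for paired designs). Designed so the
    asymmetry between perception of temperature decreases and increases can be
    reproduced mechanically from a convex stimulus-response function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
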