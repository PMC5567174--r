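Package: flexitorque
Title: Circumference-Driven Modelling of Elbow Flexion Torque
Version: 0.1.0
Authors@R:
    person("flexitorque", "developers", email = "flexitorque@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of elbow flexion dynamometry driven by
    upper-arm circumferential strain. Provides a forward simulator for
    isokinetic, isotonic and passive flexion trials with known ground truth;
    calibration of the connatural (passive) circumference profile;
    rectification of drifting circumference signals and extraction of the
    voluntary circumferential strain; estimation of the combined
    torque-angle/torque-velocity factor eta = T/s and its log-linear fit over
    the stable angle range; one-way ANOVA with eta-squared effect sizes for
    testing velocity independence; torque prediction from an averaged eta
    model; and the five standard torque-error indicators. A study driver and
    command-line interface reproduce the whole protocol end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
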