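Package: gaitbalance
Title: Balance-Impairment Detection from Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes cohort-scale treadmill walking data with known
    ground truth (heel strikes, step geometry, a linear foot-placement law,
    an injected divergence rate and pelvis perturbations), computes six
    balance metrics from marker, force-plate and center-of-pressure signals
    (step-width variability, step-time variability, foot-placement
    predictability, short-term maximum Lyapunov exponent, lateral margin of
    stability and perturbation-induced center-of-mass displacement), and
    evaluates how accurately each metric detects impaired balance under
    subject-specific versus cohort-based detection thresholds, with
    bootstrap uncertainty and nonparametric statistical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
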