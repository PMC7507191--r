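Package: tempobisect
Title: Audio-Visual Temporal Bisection: Simulation, Psychometric Fitting
    and Optimal Cue-Combination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates audio, visual and bimodal temporal-bisection
    experiments with conflict stimuli and QUEST adaptive trial placement,
    fits cumulative-Gaussian psychometric functions (point of subjective
    equality and discrimination threshold with bootstrap standard errors),
    computes maximum-likelihood cue-combination predictions for bimodal
    thresholds and conflict-induced bias shifts, and runs cohort-level
    comparisons (pooled bimodal thresholds, observed-versus-predicted
    paired tests, correlations with age and reading measures, and
    correlation-difference z tests) on synthetic cohorts emulating typical
    and dyslexic children. Ships a clinical covariate table as a
    plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
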