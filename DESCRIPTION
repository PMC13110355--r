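Package: gazebias
Title: Gaze-Mediated Bias Analysis for Psychophysics and Eye-Movement Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how motivation and gaze behaviour shape
    perceptual decisions. Implements smooth-pursuit oculometrics
    (zero-phase filtering, saccade detection and desaccading, pursuit
    velocity summaries and oculometric decisions), maximum-likelihood
    psychometric function fitting with point-of-subjective-equality bias
    indices, signal-detection analysis with gaze-endpoint
    residualisation, a Bayesian adaptive (QUEST) contrast staircase with
    an attentional imbalance score, cluster-based and label permutation
    tests on reversal-aligned gaze time courses, group-level inference
    (effect sizes with noncentral-t confidence intervals, default-prior
    Bayes factors, questionnaire scoring), and synthetic observers that
    simulate all four experimental designs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
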