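Package: moodcast
Title: Personalised, Explainable Mood-Score Prediction from Wearable and EMA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for building personalised models of ordinal depressed-mood
    scores (1-7) from longitudinal wearable, ecological-momentary-assessment (EMA)
    and neurocognitive features. Provides a seeded synthetic-cohort generator with
    planted effects, realistic missingness and constant-sensor artifacts; three
    missing-data schemes (deletion, type-aware manual imputation, and automatic
    per-feature imputation selected by the two-sample Kolmogorov-Smirnov statistic
    over seven fill methods); multilayer-perceptron classification and regression
    of the mood score under stratified 5-fold cross-validation with Adam training
    and early stopping; evolutionary hyperparameter optimisation (random, 1+1,
    PSO, DE, ES, CMA-ES, LHS-initialised Bayesian-style refinement) over the
    architecture search space; and post hoc model explanation via exact and kernel
    Shapley values, accumulated local effects (ALE) curves, and anchor IF-THEN
    rules with precision and coverage, including a before/after rule comparison
    around anomalous mood jumps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
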