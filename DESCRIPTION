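Package: surgskill
Title: Surgical Skill Assessment from Wearable EMG and Accelerometer Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for classifying surgical skill
    levels (novice, intermediate, expert) from wearable sensors worn during
    basic surgical tasks.  Implements surface-EMG envelope preprocessing
    (detrend, band-pass, mains notch, windowed RMS rectification, low-pass,
    MVC normalization), muscular-workload and activation-timing features,
    nonlinear movement-variability features of resultant acceleration
    (approximate/sample/multiscale entropy, Grassberger-Procaccia correlation
    dimension, Rosenstein and Wolf largest Lyapunov exponents, generalized
    Hurst exponent), correlation-based and recursive-feature-elimination
    feature selection, and per-muscle / muscle-combination evaluation of
    random-forest, SVM and naive-Bayes classifiers with one-vs-rest ROC.
    A synthetic-cohort generator with skill-dependent muscle-activation and
    movement-complexity profiles makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
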