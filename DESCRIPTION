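Package: bcghyper
Title: Hypertension Detection from Ballistocardiograph Signals with Hybrid
    Boosted Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A configurable pipeline for binary classification of hypertension
    from mattress-sensor ballistocardiograph (BCG) waveforms. Provides a
    synthetic two-class BCG cohort generator, waveform input/output with ICA
    artifact cleaning and fixed-window segmentation, five feature extractors
    (K-means frame clustering, maximal-overlap discrete wavelet transform,
    empirical wavelet transform, kernel principal components, random feature
    mapping with lasso fine-tuning), filter and binary-metaheuristic wrapper
    feature selection (information gain, binary tunicate swarm, Aquila
    optimizer, and chi-square/correlation/PSO/ACO baselines), four hybrid
    boosted classifiers (AdaBoost-MULDA, AdaBoost-random-forest,
    ARIMA-AdaBoost, time-weighted AdaBoost-SVM), and subject-stratified
    10-fold cross-validated evaluation with a results grid and a feature
    statistics battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    rpart,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
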