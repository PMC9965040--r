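Package: erpdecode
Title: Single-Trial Decoding of Visual Oddball ERPs with Age-Structured Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-trial classification of
    visual oddball EEG epochs. Generates age-structured synthetic event-related
    potential (ERP) data with Gaussian-bump components (P1, N170, P2, P3),
    pink-plus-white trial noise and artifact epochs; performs amplitude-based
    epoch rejection and electrode-cluster averaging; extracts a 40-feature
    temporal dataset (cluster amplitudes plus short-time Fourier spectral power)
    and a 16-feature time-independent statistical ERP dataset (peak amplitude,
    mean amplitude, peak latency, fractional 50 percent peak latency); selects
    features by a nearest-neighbour mutual-information estimator; runs
    per-participant imbalance-aware 10-fold cross-validated classification
    (SMOTE-style oversampling, min-max scaling, nine classifiers) per time point
    or on static features; and compares classifiers with Friedman tests,
    Holm-corrected pairwise Wilcoxon tests, Nemenyi critical-difference diagrams
    and their time-resolved extension, age-group tests, and permutation feature
    importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    class,
    e1071,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils,
    graphics,
    grDevices,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
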