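Package: vqerds
Title: Vector-Quantized Entropy Estimation of Event-Related
    Desynchronization in Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-trial extraction of event-related
    desynchronization/synchronization (ERD/S) time-courses from
    multichannel motor-imagery EEG. Implements the classical band-power
    ratio estimator together with three entropy-based estimators on
    delay-embedded sliding windows: sample entropy, fuzzy entropy, and a
    vector-quantized entropy (VQEnt) that takes the Shannon entropy of a
    Bayesian posterior over a greedily built codebook of delay vectors
    with Gaussian-similarity likelihoods. Includes Butterworth band-pass
    and surface-Laplacian preprocessing, a synthetic two-class
    motor-imagery EEG generator with known ERD ground truth, and the
    downstream analyses: parameter-grid tuning, LDA cross-validated
    discrimination, trial-similarity matrices, channel relevance
    ranking, incremental channel selection, and cluster-based
    permutation testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
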