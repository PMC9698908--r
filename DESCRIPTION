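Package: ppgaffect
Title: Morphological PPG Features, Synthetic Pulse Cohorts, and SVM-Based
    Emotion-State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for affective computing from single-channel
    photoplethysmography (PPG). Implements beat-level pulse-wave delineation
    (blood volume amplitude, systolic upstroke time, diastolic time, and
    peak-to-peak / valley-to-valley intervals), 30-second segment
    featurization with differential (baseline-subtracted) features,
    leakage-free z-score normalization, wrapper feature selection by
    exhaustive search or a genetic algorithm, and one-against-all RBF
    support-vector-machine classification validated by resubstitution and
    segment-wise six-fold cross-validation. Includes a synthetic PPG cohort
    generator with beat-level ground truth so the whole pipeline can be
    exercised and tested without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
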