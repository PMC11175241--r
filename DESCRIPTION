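Package: ssvepkiosk
Title: Multimodal EEG-SSVEP and Virtual-Kiosk Screening Pipeline for
    Amnestic Mild Cognitive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multimodal screening of
    amnestic mild cognitive impairment (aMCI). Generates synthetic
    intermittent-photic-stimulation EEG with steady-state visual evoked
    potential (SSVEP) responses, virtual-kiosk behavioral session logs, and
    cross-modally correlated feature tables; extracts harmonic lobe-power
    ratios and weighted-phase-lag-index connectivity ratios over the dorsal
    stream (multitaper time-frequency, Onnela weighted clustering
    coefficient); computes six virtual-kiosk behavioral features; runs a
    sequential group-comparison ladder with Benjamini-Hochberg correction
    and cross-modal Pearson correlations; and benchmarks embedded
    linear-SVM feature selection with leave-one-out cross-validated
    classifiers on unimodal and combined feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    kernlab,
    class,
    randomForest,
    car,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
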