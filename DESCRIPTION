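Package: spikeripples
Title: Interictal Spike and High-Frequency Oscillation Co-Occurrence
    Analysis for Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects interictal spikes, ripples (80-250 Hz) and fast
    ripples (250-500 Hz) on intracranial EEG, classifies their temporal
    co-occurrence within a +/- 50 ms window into eleven biomarker
    categories, and evaluates each category's ability to localize the
    seizure-onset zone and resected area (restricted-specificity partial
    AUC, sensitivity at fixed specificity) and to predict surgical
    outcome through the resection ratio (Youden-point metrics,
    leave-one-out cross-validation, Barnard's exact unconditional test,
    pseudo-prospective prediction at a fixed cut-off). Includes a
    synthetic-cohort generator emulating interictal recordings with 1/f
    background, embedded spikes and band-limited oscillation bursts, a
    Hilbert-envelope HFO detector with automated quality control, a
    stand-in spike detector, EDF and delimited-text I/O, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
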