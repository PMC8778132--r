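Package: resbilstm
Title: Residual-CNN BiLSTM Classification of Human Activities from
    Inertial Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for human activity recognition (HAR) from
    multi-channel inertial measurement unit (IMU) time series: readers for
    common on-disk formats (WISDM raw text, PAMAP2 protocol files, generic
    labelled CSV), per-channel z-score standardization, overlapping
    sliding-window segmentation, a residual convolutional block feeding a
    bidirectional LSTM classifier trained from scratch with Adam, confusion
    matrix based evaluation (per-class precision/recall/F1 and
    support-weighted F1), hyperparameter sweeps, and a seeded synthetic IMU
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
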