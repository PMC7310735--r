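Package: anxiodetect
Title: On-Line Anxiety Level Detection from Wearable Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing of electrocardiogram (ECG), electrodermal activity
    (EDA) and respiration (RSP) recordings from wearable sensors, extraction
    of 25 time-domain features, ten data-labeling approaches for two- and
    three-level anxiety classes, classifier training with 10-fold
    cross-validation (accuracy, per-class true rates, ROC/AUC, Cohen's
    kappa), sequential forward feature selection, and a playback engine that
    emulates real-time acquisition with a prediction every 10 seconds. A
    synthetic arousal-session simulator with full ground truth makes every
    stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    data.table,
    MASS,
    rpart,
    caret,
    e1071,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
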