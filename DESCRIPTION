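Package: cardiosleep
Title: Single-Epoch Sleep-Wake Classification and Sleep Apnea Screening
    from Cardiorespiratory Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates sleep-wake state of suspected obstructive sleep
    apnea (OSA) patients from single 30-second epochs of ECG and thoracic
    respiratory-effort (RIP) signals. Provides instantaneous-heart-rate
    tachogram and respiratory-effort preprocessing with per-segment
    quality control, a multimodal one-dimensional convolutional network
    with frozen-branch fusion trained on balanced batches, total sleep
    time estimation, posterior-confidence uncertainty metrics, an
    ROC-based decision rule that flags likely OSA patients from the
    predicted sleep architecture, and a synthetic polysomnography cohort
    generator for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC
Config/testthat/edition: 3
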