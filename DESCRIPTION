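Package: fallnet
Title: Pre-Impact Fall Prediction from Wearable Inertial Sensors with
    Convolutional-Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting a fall during its descent phase, before
    body-ground impact, from waist-worn accelerometer and gyroscope
    recordings sampled at 200 Hz. Recordings are labeled into three stages
    (non-fall, pre-impact fall, fall), segmented into fixed-length
    overlapping windows, and classified with three network families: a
    convolutional network, a stacked LSTM, and a hybrid ConvLSTM that feeds
    convolutional feature maps into recurrent layers. Training uses focal
    loss under heavy class imbalance, subject-wise five-fold
    cross-validation, and a top-3 summation-sensitivity epoch-selection
    rule; evaluation reports one-vs-rest sensitivity, specificity and
    accuracy per class plus per-instance inference latency. A built-in
    synthetic IMU cohort generator emulates the SisFall file dialect and
    the three-stage fall structure so the whole pipeline is testable
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
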