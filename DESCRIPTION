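Package: gaitphase
Title: Gait Phase Classification from Shank-Mounted IMU Time Series
Version: 0.1.0
Authors@R: person("Wonseok", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for detecting gait events (heel strike, toe off) from
    bilateral foot-contact signals, labeling the four gait phases (Loading
    Response, Late Stance, Pre-Swing, Swing) of a reference leg, building
    sliding-window one-step-ahead training samples from shank inertial
    measurement unit (IMU) signals, and training and comparing three sequence
    classifiers (a one-dimensional convolutional network, a hybrid
    LSTM+GRU recurrent network, and a Transformer encoder) under a
    subject-wise evaluation protocol with macro-averaged metrics and
    confusion matrices. Includes a synthetic bilateral gait generator with
    known ground-truth events and phases so the full pipeline is testable
    without any external recordings, and a command-line interface binding
    the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
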