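Package: fbcsprnn
Title: Filter-Bank CSP and Recurrent Networks for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end classification of motor-imagery EEG trials.
    Spatial-frequency features are extracted with a Butterworth filter bank
    and common spatial patterns (CSP, with a one-versus-rest multi-class
    extension), turned into many labelled time slices by a sliding-window
    cropping strategy, and classified by gated recurrent networks (vanilla
    RNN, LSTM with peepholes, GRU) trained with backpropagation through time
    and Adam. Includes an SVM band-power baseline, paired-comparison
    statistics, and a synthetic ERD/ERS generator so the whole pipeline is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
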