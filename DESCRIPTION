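Package: cecgstress
Title: Driver Stress Detection from Capacitive ECG
Version: 0.1.0
Authors@R: person("cecgstress", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: End-to-end toolkit for detecting driver stress levels from
    single-channel capacitive ECG (cECG). Implements segment-wise artifact
    elimination based on detrended-fluctuation statistics of the
    cumulative-sum profile, extraction of four beat-level features (R-peak
    value, heart rate, pNN50 and binarized approximate entropy), and binary
    stress classification with kNN, an RBF-kernel SVM and a two-hidden-layer
    feed-forward network, evaluated with subject-grouped cross-validation
    and balanced-accuracy / Matthews-correlation metrics. Ships a synthetic
    cECG generator with per-sample ground truth so the whole pipeline is
    testable without external recordings, plus CSV/WFDB readers and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
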