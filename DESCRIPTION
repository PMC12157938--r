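Package: ewtbci
Title: EEG Motor-Execution Gesture Classification via Empirical Wavelet and
    Hilbert-Huang Features
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for one-vs-rest classification of hand
    gestures from multichannel EEG recorded during motor execution. Provides a
    deterministic synthetic EEG generator (mu/beta AM-FM components over pink
    background noise with a mains line component), Butterworth notch/bandpass
    preprocessing with sliding-window segmentation, a 1-D empirical wavelet
    transform (adaptive Meyer-type filter bank with tight-frame guarantees),
    Hilbert-Huang instantaneous amplitude/frequency extraction, higher-order
    statistics and bandpower features, three classifier families (shrinkage
    LDA, RBF support vector machine, and a hybrid 1-D CNN + bidirectional LSTM
    network implemented natively), and a k-fold cross-validated evaluation
    harness with accuracy/F1 metrics and exact Wilcoxon signed-rank model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
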