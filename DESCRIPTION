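Package: eegemo
Title: Positive/Negative Emotion Classification from Multi-Channel and
    Dual-Frontal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Pipeline for binary (positive vs negative) emotion
    classification from epoched EEG. Provides a synthetic emotional-EEG
    generator with class-dependent band-power structure, preprocessing
    (band-pass/notch filtering, average re-referencing, ICA ocular
    correction, EEMD-based cleaning for dual-frontal recordings,
    segmentation, amplitude rejection), a 59-feature per-channel
    descriptor set built around band-wise differential entropy,
    gradient-boosting electrode selection by feature contribution rate,
    and stratified 10-fold cross-validated comparison of four
    classifiers (linear SVM, gain-ratio decision tree, back-propagation
    neural network, brute-force kNN) in pooled and per-subject schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    e1071,
    nnet,
    class,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
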