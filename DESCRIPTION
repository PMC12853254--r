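Package: phonodyn
Title: Temporal-Generalization Decoding of Phonetic Features from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the neural dynamics of phoneme encoding in
    continuous-speech EEG. Provides a synthetic-EEG generator with a known
    dynamic-coding ground truth (feature-locked spatial patterns that are
    handed between neural ensembles at a configurable dwell time), phonetic
    feature annotation with cohort-entropy conditions, the standard EEG
    conditioning chain (common-average reference, least-squares FIR filters,
    resampling, normalization, phoneme-locked epoching), temporal
    generalization decoding with one-vs-all ridge logistic regression,
    generalization-width and dynamic-coding metrics, and cluster-based
    permutation statistics (sign-flip, group exchange, max-t sensor tests,
    FDR-corrected interaction tests).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
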