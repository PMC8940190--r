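Package: pathovoice
Title: Pathological Voice Disorder Classification from Continuous Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A frame-level machine-learning pipeline for classifying common
    voice disorders (functional dysphonia, neoplasm, phonotrauma, vocal palsy)
    from acoustic recordings of sustained vowels and continuous speech.
    Includes a synthetic dysphonic-voice corpus generator (source-filter
    synthesis with controllable jitter, shimmer, harmonics-to-noise ratio and
    pitch instability), a Gaussian statistical-model voice activity detector
    with decision-directed SNR estimation, a 26-dimensional MFCC+delta front
    end, five frame-level classifiers (DNN, LSTM, BiLSTM, GRU, random forest)
    with majority-vote utterance inference, and accuracy / per-class
    sensitivity / unweighted-average-recall evaluation with experiment
    harnesses for condition comparison, sentence selection and PCA feature
    visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    randomForest,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
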