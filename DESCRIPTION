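Package: aptranslate
Title: Multitask LSTM Translation of Immature Cardiomyocyte Action
    Potentials into Adult Ventricular Action Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of noisy immature (iPSC-CM-like,
    spontaneously beating) and adult ventricular action potentials from a
    reduced Hodgkin-Huxley-style ionic model with a stochastic noise
    current and two hERG (IKr) drug-block schemes (conductance scaling and
    state-dependent open-channel binding).  Trains a from-scratch
    two-layer LSTM multitask network that translates immature action
    potentials into adult ones while classifying traces as drug-free or
    drugged, with zero-phase preprocessing, ADAM optimisation, evaluation
    metrics (MSE, R2, APD90 error, AUROC, accuracy, precision, recall),
    and time-window feature ablation plus model-component ablation
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
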