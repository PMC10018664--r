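Package: respredict
Title: Respiratory Motion Prediction for Latency Compensation in Robotic Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, supervised-dataset construction, training and evaluation of
    recurrent neural-network predictors of respiratory motion, as used to compensate
    the beam-delivery latency of robotic tumour-tracking radiotherapy systems. Provides
    a Lujan-type breathing-signal simulator with five qualitative breathing regimes,
    chronological train/validation/test splitting, latency-shifted sliding-window
    dataset construction, a compact recurrent-network engine (simple RNN, LSTM, GRU,
    their bidirectional variants and a CNN-LSTM, with vector or encoder-decoder
    multistep heads) trained by backpropagation through time, a grouped
    (nonsequential-correlated) hyperparameter search, and an evaluation suite
    (RMSE, MAE, NRMSE, variance-ratio F-test, box-plot statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
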