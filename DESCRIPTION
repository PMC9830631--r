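Package: csibreathe
Title: Contactless Respiratory Motion Classification from Wi-Fi Channel State
    Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates breathing-modulated Wi-Fi channel state information
    (CSI) for a MIMO-OFDM link using a multipath channel model in which chest
    displacement modulates the delay of a reflected path, and classifies
    respiratory patterns and rates from the resulting complex CSI streams.
    Provides FFT-based spectral preprocessing with per-stream
    standardization, a bidirectional LSTM sequence classifier trained with
    cross-entropy and Adam (with an Armadillo training core), complete
    confusion-matrix metrics (per-class and macro precision, recall,
    specificity, F1) with stratified k-fold cross-validation, a free-space
    path-loss link budget, and characterization sweeps over added
    attenuation, acquisition length and frame rate. Includes a binary
    container format for CSI tensors, datasets and models, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
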