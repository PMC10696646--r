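Package: ecgbeats
Title: Real-Time ECG Beat Classification with Image-Based Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for arrhythmia detection from annotated electrocardiogram (ECG)
    recordings. Reads and writes WFDB-dialect records, extracts fixed-length beat
    windows around R-peak annotations, encodes each window as a sparse binary image
    by floor quantization (one lit pixel per signal sample), and classifies beats
    with compact 2D convolutional neural networks trained by backpropagation.
    Includes a streaming detector that simulates a fixed-rate sample source feeding
    a ring buffer, with exact accounting of samples skipped while the classifier is
    busy, and a synthetic ECG generator with controllable beat morphologies so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    png,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
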