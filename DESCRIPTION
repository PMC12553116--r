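Package: acwte
Title: Dynamic Intrinsic Timescales and Semantics-to-Brain Transfer Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying information transfer from the fluctuating
    timescales of naturalistic speech semantics to the fluctuating intrinsic
    timescales of brain signals. Builds 1-Hz semantic time-series from timed
    transcripts (word hypernym depth, windowed sentence-embedding similarity),
    estimates dynamic autocorrelation windows (ACW-0/ACW-50/ACW-e) in sliding
    windows after zero-phase Butterworth band-pass filtering, and tests lagged
    transfer entropy between the resulting timescale series with a
    Kraskov-Stoegbauer-Grassberger k-nearest-neighbour estimator and Markov
    block-bootstrap surrogates. Also provides sliding-window inter-subject
    correlation, region-by-region correlation matrices, Levene variance
    contrasts, Welch power spectral densities, and a synthetic-data generator
    with ground-truth timescale coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
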