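Package: critsample
Title: Sampling Effects and Measurement Overlap in Neuronal Avalanche
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a locally-connected branching network of binary
    neurons sampled by a grid of virtual electrodes, emulating both
    coarse (LFP-like) recordings and spike sub-sampling, and provides
    the complete neuronal-avalanche analysis pipeline: band-pass
    filtering and threshold-based event extraction, temporal binning,
    avalanche decomposition, discrete power-law fitting, bin-size
    scaling of the fitted exponent, and avalanche-based estimation of
    the branching parameter. Designed to quantify how inter-electrode
    distance, electrode field of view and time-bin size bias the
    inference of the underlying dynamic state.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
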