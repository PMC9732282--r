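Package: rovingmmn
Title: Roving-Oddball Mismatch Negativity Analysis with Bayesian Surprise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing roving-oddball auditory EEG
    studies of implicit perceptual learning: generation and validation of
    pitch-alternating stimulus-train sequences, a sequential Bayesian ideal
    observer yielding per-trial Bayesian surprise, a synthetic study
    generator (ERP component templates, surprise-scaled mismatch responses,
    binomial behavioural scores), mismatch-negativity differential waves
    with last-standard selection, trial-by-trial surprise-EEG correlation
    maps, spatiotemporal cluster-based permutation statistics, and paired
    behavioural tests with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
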