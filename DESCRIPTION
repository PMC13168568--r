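Package: speechtrf
Title: Temporal Response Functions for Continuous Speech with
    Cohort-Model Phoneme Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward ("encoding") models of neural responses to continuous
    speech. Computes cohort-model phoneme statistics (conditional probability,
    surprisal, entropy) from frequency-weighted pronunciation lexicons,
    gammatone spectrograms and acoustic-edge (onset) spectrograms on an
    ERB-spaced filterbank, and assembles trial-structured predictor sets on a
    100 Hz grid with a lagged Hamming-window basis.  Temporal response
    functions are estimated by coordinate-wise boosting with cross-validation
    and early stopping; feature contributions are quantified by ablation of
    feature families, and group-level inference uses one-sample t tests,
    cluster-based sign-flip permutation tests across lag, and peak-latency
    extraction.  A synthetic-data module generates isochronous syllable
    streams, toy lexicons and simulated multi-subject source responses with
    known ground-truth kernels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
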