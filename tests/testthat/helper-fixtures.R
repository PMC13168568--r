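# Small fixtures built in code.

# the worked-example lexicon {ba:2, bi:1, da:1}
toy_lexicon <- function() {
  lexicon(c("ba", "bi", "da"), c(2, 1, 1),
          list(c("b", "a"), c("b", "i"), c("d", "a")))
}

# random lexicon with variable-length phoneme sequences
random_lexicon <- function(n_words, seed, max_len = 5) {
  set.seed(seed)
  inv <- letters[1:6]
  phon <- lapply(seq_len(n_words), function(i) {
    sample(inv, sample(2:max_len, 1), replace = TRUE)
  })
  words <- vapply(seq_len(n_words), function(i) {
    paste0(paste(phon[[i]], collapse = ""), letters[(i %% 26) + 1], i %/% 26 + 1)
  }, character(1))
  words <- gsub("[0-9]", "q", words)  # keep forms alphabetic and unique
  lexicon(words, sample(1:20, n_words, replace = TRUE), phon,
          case = "preserve")
}

# small multi-trial predictor set of independent channels
random_predictor_set <- function(seed, n_trials = 8, len = 300,
                                 families = c("f1", "f2", "f3")) {
  set.seed(seed)
  C <- length(families)
  mats <- lapply(seq_len(n_trials), function(i) {
    m <- vapply(seq_len(C), function(ci) {
      if (ci %% 2 == 0) {
        x <- numeric(len)
        x[sample(len, max(5, len %/% 15))] <- rexp(max(5, len %/% 15))
        x
      } else {
        x <- as.numeric(stats::filter(rnorm(len), rep(1 / 4, 4), sides = 2))
        x[is.na(x)] <- 0
        x
      }
    }, numeric(len))
    colnames(m) <- families
    m
  })
  ends <- cumsum(rep(len, n_trials))
  predictor_set(do.call(rbind, mats), families,
                trials = tibble::tibble(trial = seq_len(n_trials),
                                        start = ends - len + 1L, end = ends))
}

# ready-to-fit design + truth + response at a given SNR
recovery_instance <- function(seed, snr = 0.5, n_trials = 8, len = 400) {
  ps <- normalize_channels(random_predictor_set(seed, n_trials, len))
  ps <- pad_trials(ps)
  des <- lag_expand(ps)
  tr <- ground_truth(des$cols, family_spec = list(
    f1 = list(peak_ms = 100, amplitude = 1),
    f2 = list(peak_ms = 400, amplitude = 1),
    f3 = list(peak_ms = 250, amplitude = 0.7)
  ), seed = seed)
  resp <- simulate_responses(des, tr, n_subjects = 1, n_sources = 1,
                             snr = snr, seed = seed + 1000)[[1]]
  list(design = des, truth = tr, response = normalize_channels(resp))
}
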