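test_that("toy lexicons are reproducible CV-CV words with Zipf frequencies", {
  lex <- make_toy_lexicon(n_words = 20, seed = 2)
  expect_equal(nrow(lex), 20)
  expect_true(all(vapply(lex$phonemes, length, integer(1)) == 4))
  expect_true(all(diff(lex$frequency) <= 0))
  lex2 <- make_toy_lexicon(n_words = 20, seed = 2)
  expect_identical(lex$word, lex2$word)
  expect_identical(lex$frequency, lex2$frequency)

  one <- make_toy_lexicon(n_words = 1, seed = 3)
  prof <- word_surprisal_profile(one, one$phonemes[[1]])
  expect_equal(prof$surprisal_bits, rep(0, 4))

  expect_error(make_toy_lexicon(n_words = 10, n_consonants = 1,
                                n_vowels = 2, seed = 1),
               "Inventory too small|exceeds")
})

test_that("a 16-syllable 250 ms sequence lasts exactly 4 seconds", {
  lex <- make_toy_lexicon(seed = 4)
  st <- make_streams(lex, "words", n_sequences = 2, seed = 4)
  sq <- st[[1]]
  expect_equal(length(sq$audio$samples) / sq$audio$rate, 4)
  expect_equal(max(sq$events$onset_s) < 4, TRUE)
  # word onsets at even syllable indices x 250 ms
  wo <- sq$events$onset_s[sq$events$tier == "word"]
  expect_equal(wo, seq(0, 3.5, by = 0.5))
  # sound level normalised to -15 dBFS RMS
  expect_equal(20 * log10(sqrt(mean(sq$audio$samples^2))), -15,
               tolerance = 1e-6)
})

test_that("random-syllable streams permute the words streams' syllables", {
  lex <- make_toy_lexicon(seed = 6)
  w <- make_streams(lex, "words", n_sequences = 3, seed = 6)
  r <- make_streams(lex, "random_syllables", n_sequences = 3, seed = 6)
  for (i in 1:3) {
    expect_equal(sort(w[[i]]$syllables), sort(r[[i]]$syllables))
  }
  # determinism
  r2 <- make_streams(lex, "random_syllables", n_sequences = 3, seed = 6)
  expect_identical(r[[1]]$syllables, r2[[1]]$syllables)
  expect_identical(r[[1]]$audio$samples, r2[[1]]$audio$samples)
})

test_that("word lists shuffle sentence templates", {
  lex <- make_toy_lexicon(seed = 7)
  se <- make_streams(lex, "sentences", n_sequences = 2, seed = 7)
  wl <- make_streams(lex, "word_list", n_sequences = 2, seed = 7)
  roles <- (seq_len(nrow(lex)) - 1L) %% 4L + 1L
  role_of <- setNames(roles, lex$word)
  # sentences follow the fixed role template 1,2,3,4 repeating
  expect_equal(unname(role_of[se[[1]]$words]), rep(1:4, 2))
  # the word list uses the same words per sequence position count
  expect_equal(length(wl[[1]]$words), 8)
})

test_that("ground-truth kernels vanish at negative lags and scale by condition", {
  cols <- tidyr::expand_grid(channel = c("x1", "x2"), lag_ms = lag_axis())
  cols$family <- rep(c("acoustic_edges", "phoneme"), each = 75)
  cols$lag_samples <- rep(round(lag_axis() / 10), 2)
  mod <- tibble::tibble(family = "phoneme", condition = "boost",
                        factor = 1.5, window_lo_ms = -Inf,
                        window_hi_ms = Inf)
  tr <- ground_truth(cols, modulation = mod, seed = 5)
  expect_true(all(tr$base[cols$lag_ms <= 0] == 0))
  k <- truth_kernel(tr, "boost")
  ph <- cols$family == "phoneme"
  expect_equal(k[ph], 1.5 * tr$base[ph])
  expect_equal(k[!ph], tr$base[!ph])
  # windowed modulation touches only the window
  mod2 <- tibble::tibble(family = "acoustic_edges", condition = "c",
                         factor = 2, window_lo_ms = 0, window_hi_ms = 100)
  tr2 <- ground_truth(cols, modulation = mod2, seed = 5)
  k2 <- truth_kernel(tr2, "c")
  inwin <- cols$family == "acoustic_edges" & cols$lag_ms >= 0 &
    cols$lag_ms <= 100
  expect_equal(k2[inwin], 2 * tr2$base[inwin])
  outwin <- cols$family == "acoustic_edges" & !inwin
  expect_equal(k2[outwin], tr2$base[outwin])
})

test_that("noiseless simulation equals the double-loop convolution oracle", {
  set.seed(13)
  channels <- cbind(u = rnorm(300), v = rnorm(300))
  ps <- predictor_set(channels, c("fu", "fv"))
  des <- lag_expand(ps)
  tr <- ground_truth(des$cols, family_spec = list(
    fu = list(peak_ms = 100, amplitude = 1),
    fv = list(peak_ms = 300, amplitude = 0.5)
  ), seed = 13)
  resp <- simulate_responses(des, tr, n_subjects = 1, n_sources = 1,
                             snr = Inf, seed = 14)[[1]]
  gain <- resp$values[50, 1] /
    drop(des$X %*% tr$base)[50]  # per-source gain is deterministic given seed
  beta_mat <- t(matrix(tr$base, nrow = 75))
  y_oracle <- oracle_forward(channels, beta_mat,
                             unique(des$cols$lag_samples), hamming5()) * gain
  expect_lt(max(abs(resp$values[, 1] - y_oracle)), 1e-9)
})

test_that("the realised SNR matches the requested ratio", {
  set.seed(15)
  channels <- cbind(a = as.numeric(stats::filter(rnorm(10000), rep(0.2, 5),
                                                 sides = 2)))
  channels[is.na(channels)] <- 0
  ps <- predictor_set(channels, "fa")
  des <- lag_expand(ps)
  tr <- ground_truth(des$cols,
                     family_spec = list(fa = list(peak_ms = 150,
                                                  amplitude = 1)),
                     seed = 15)
  clean <- simulate_responses(des, tr, n_subjects = 1, n_sources = 1, snr = Inf, seed = 16)[[1]]$values
  noisy <- simulate_responses(des, tr, n_subjects = 1, n_sources = 1, snr = 2, seed = 16)[[1]]$values
  snr_hat <- var(clean[, 1]) / var(noisy[, 1] - clean[, 1])
  expect_equal(snr_hat, 2, tolerance = 0.1)
})

test_that("experiment bundles are deterministic and structurally complete", {
  e1 <- make_experiment("null", seed = 9, n_subjects = 2, n_sources = 2,
                        n_sequences = 5)
  e2 <- make_experiment("null", seed = 9, n_subjects = 2, n_sources = 2,
                        n_sequences = 5)
  expect_identical(yaml::as.yaml(e1$manifest), yaml::as.yaml(e2$manifest))
  expect_identical(e1$responses[["words"]][[1]]$values,
                   e2$responses[["words"]][[1]]$values)
  expect_setequal(e1$conditions, c("words", "random_syllables"))
  expect_length(e1$predictors[["words"]], 2)
  # familiarity contrast reuses each subject's streams in both conditions
  ef <- make_experiment("familiarity", seed = 9, n_subjects = 1,
                        n_sources = 1, n_sequences = 5)
  expect_identical(ef$streams[["native"]][[1]][[1]]$audio$samples,
                   ef$streams[["unfamiliar"]][[1]][[1]]$audio$samples)
})
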