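test_that("worked cohort example matches hand enumeration", {
  lex <- toy_lexicon()
  st <- cohort_init(lex)
  expect_equal(st$mass, 4)

  s1 <- advance_cohort(lex, st, "b")
  expect_equal(s1$probability, 3 / 4)
  expect_setequal(lex$word[s1$state$members], c("ba", "bi"))

  s2 <- advance_cohort(lex, s1$state, "a")
  expect_equal(s2$probability, 2 / 3)
  expect_setequal(lex$word[s2$state$members], "ba")

  expect_equal(next_phoneme_entropy(lex, s1$state),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3),
               tolerance = 1e-12)

  prof <- word_surprisal_profile(lex, c("b", "a"))
  expect_equal(prof$surprisal_bits, c(-log2(3 / 4), -log2(2 / 3)),
               tolerance = 1e-12)
  # telescoping: total surprisal of "ba" = -log2(freq/total)
  expect_equal(sum(prof$surprisal_bits), -log2(2 / 4), tolerance = 1e-12)
})

test_that("surprisal = -log2(probability) for every record", {
  lex <- random_lexicon(30, seed = 4)
  for (w in sample(seq_len(nrow(lex)), 5)) {
    prof <- word_surprisal_profile(lex, lex$phonemes[[w]])
    expect_equal(prof$surprisal_bits, -log2(prof$probability),
                 tolerance = 1e-12)
    expect_true(all(prof$entropy_bits >= 0))
  }
})

test_that("single-word lexicon yields probability 1 and zero surprisal", {
  lex <- lexicon("ba", 5, list(c("b", "a")))
  prof <- word_surprisal_profile(lex, c("b", "a"))
  expect_equal(prof$probability, c(1, 1))
  expect_equal(prof$surprisal_bits, c(0, 0))
  expect_false(any(prof$fallback))
})

test_that("entropy handles deterministic and uniform continuations", {
  # deterministic: single continuation -> 0 bits
  lex <- lexicon(c("ba", "da"), c(2, 1), list(c("b", "a"), c("d", "a")))
  s <- advance_cohort(lex, cohort_init(lex), "b")$state
  expect_equal(next_phoneme_entropy(lex, s), 0)
  # uniform binary continuation -> 1 bit
  lex2 <- lexicon(c("ba", "bi"), c(3, 3), list(c("b", "a"), c("b", "i")))
  s2 <- advance_cohort(lex2, cohort_init(lex2), "b")$state
  expect_equal(next_phoneme_entropy(lex2, s2), 1)
})

test_that("word-end outcome keeps prefix-word distributions proper", {
  # "ba" is a prefix of "bad": after 'b','a' the cohort has an exact match
  lex <- lexicon(c("ba", "bad"), c(1, 1),
                 list(c("b", "a"), c("b", "a", "d")))
  s <- advance_cohort(lex, cohort_init(lex), "b")$state
  s <- advance_cohort(lex, s, "a")$state
  expect_equal(next_phoneme_entropy(lex, s, include_word_end = TRUE), 1)
  expect_equal(next_phoneme_entropy(lex, s, include_word_end = FALSE), 0)
})

test_that("cohort mass is non-increasing and matches enumeration oracle", {
  for (seed in 1:5) {
    lex <- random_lexicon(50, seed = seed)
    for (w in sample(seq_len(nrow(lex)), 4)) {
      word <- lex$phonemes[[w]]
      st <- cohort_init(lex)
      for (i in seq_along(word)) {
        step <- advance_cohort(lex, st, word[[i]])
        expect_lte(step$state$mass, st$mass)
        expect_equal(step$probability,
                     oracle_cond_prob(lex$word, lex$frequency, lex$phonemes,
                                      word, i),
                     tolerance = 1e-12)
        if (step$state$mass > 0) {
          expect_equal(next_phoneme_entropy(lex, step$state),
                       oracle_next_entropy(lex$word, lex$frequency,
                                           lex$phonemes, word[seq_len(i)]),
                       tolerance = 1e-12)
        }
        st <- step$state
      }
      # telescoping within 1e-9
      prof <- word_surprisal_profile(lex, word)
      expect_equal(sum(prof$surprisal_bits),
                   -log2(st$mass / attr(lex, "total_frequency")),
                   tolerance = 1e-9)
    }
  }
})

test_that("entropy respects its theoretical bounds", {
  for (seed in 6:9) {
    lex <- random_lexicon(25, seed = seed)
    upper <- log2(length(attr(lex, "inventory")) + 1)
    w <- sample(seq_len(nrow(lex)), 1)
    prof <- word_surprisal_profile(lex, lex$phonemes[[w]])
    expect_true(all(prof$entropy_bits >= 0 - 1e-12))
    expect_true(all(prof$entropy_bits <= upper + 1e-12))
  }
})

test_that("unknown phoneme symbols raise a named error", {
  lex <- toy_lexicon()
  expect_error(advance_cohort(lex, cohort_init(lex), "z"), "'z'")
})

test_that("empty-cohort fallback policies behave as documented", {
  lex <- toy_lexicon()  # inventory a, b, d, i
  st <- cohort_init(lex)
  # "di" is not a word: after 'd' only "da" remains, 'i' empties the cohort
  s1 <- advance_cohort(lex, st, "d")
  uni <- advance_cohort(lex, s1$state, "i", fallback = "uniform")
  expect_true(uni$fallback)
  expect_equal(uni$probability, 1 / 4)
  expect_equal(uni$state$mass, 0)
  # once empty, uniform fallback persists
  nxt <- advance_cohort(lex, uni$state, "b", fallback = "uniform")
  expect_true(nxt$fallback)

  # restart policy re-enters the lexicon word-initially
  res <- advance_cohort(lex, s1$state, "i", fallback = "restart")
  expect_true(res$fallback)
  expect_equal(res$state$mass, 0)  # no word starts with 'i'
  # 'b' does not continue the empty cohort; restart finds the b-initial
  # cohort (mass 3 of total 4)
  res_b2 <- advance_cohort(lex, uni$state, "b", fallback = "restart")
  expect_true(res_b2$fallback)
  expect_equal(res_b2$probability, 3 / 4)
  expect_equal(res_b2$state$mass, 3)
})

test_that("annotate_events composes the per-word oracles", {
  lex <- toy_lexicon()
  ev <- tibble::tibble(
    onset_s = c(0.0, 0.0, 0.1, 0.25, 0.25, 0.35),
    tier = c("word", "phoneme", "phoneme", "word", "phoneme", "phoneme"),
    label = c("ba", "b", "a", "da", "d", "a"),
    word_index = c(1L, 1L, 1L, 2L, 2L, 2L)
  )
  out <- annotate_events(ev, lex)
  expect_equal(nrow(out), 4)
  expect_equal(out$onset_flag, rep(1, 4))
  p1 <- word_surprisal_profile(lex, c("b", "a"))
  p2 <- word_surprisal_profile(lex, c("d", "a"))
  expect_equal(out$surprisal_bits, c(p1$surprisal_bits, p2$surprisal_bits))
  expect_equal(out$entropy_bits, c(p1$entropy_bits, p2$entropy_bits))
  expect_false(any(out$fallback))
})

test_that("annotate_events handles empty input and unknown words", {
  lex <- toy_lexicon()
  empty <- annotate_events(tibble::tibble(onset_s = numeric(0),
                                          tier = character(0),
                                          label = character(0),
                                          word_index = integer(0)), lex)
  expect_equal(nrow(empty), 0)

  # word unknown from its first phoneme: every phoneme flagged, uniform values
  ev <- tibble::tibble(onset_s = c(0, 0.1), tier = "phoneme",
                       label = c("i", "i"), word_index = 1L)
  expect_message(out <- annotate_events(ev, lex), "fallback")
  expect_true(all(out$fallback))
  expect_equal(out$surprisal_bits, rep(log2(4), 2))
  expect_equal(out$entropy_bits, rep(log2(4), 2))
})
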