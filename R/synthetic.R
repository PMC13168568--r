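#' Generate a toy frequency lexicon of bi-syllabic CV-CV words
#'
#' Words are built from a consonant and vowel inventory as two
#' consonant-vowel syllables, with Zipf-distributed integer frequencies
#' (frequency of the r-th ranked word proportional to 1/r).  Deterministic
#' under `seed`.  Stands in for corpus frequency lists at desk scale.
#'
#' @param n_words Number of distinct words (default 20).
#' @param n_consonants,n_vowels Inventory sizes (defaults 10 and 5).
#' @param seed Integer seed.
#' @return A [lexicon()] whose `syllables` attribute maps each word to its
#'   two CV syllables.
#' @export
make_toy_lexicon <- function(n_words = 20, n_consonants = 10, n_vowels = 5,
                             seed = 1) {
  consonants <- c("p", "t", "k", "b", "d", "g", "m", "n", "s", "l")[seq_len(n_consonants)]
  vowels <- c("a", "e", "i", "o", "u")[seq_len(n_vowels)]
  if (n_consonants + n_vowels < 4) abort("Inventory too small (need >= 4 symbols).")
  syllables <- as.vector(outer(consonants, vowels, paste0))
  capacity <- length(syllables)^2
  if (n_words > capacity) {
    abort(sprintf("Requested %d words exceeds the %d possible CV-CV forms.",
                  n_words, capacity))
  }
  set.seed(derive_seed(seed, "toy_lexicon"))
  pairs <- expand.grid(s1 = syllables, s2 = syllables,
                       stringsAsFactors = FALSE)
  pick <- sample(nrow(pairs), n_words)
  s1 <- pairs$s1[pick]
  s2 <- pairs$s2[pick]
  words <- paste0(s1, s2)
  freqs <- pmax(1, round(1000 / seq_len(n_words)))
  phon <- lapply(seq_len(n_words), function(i) {
    c(substr(s1[i], 1, 1), substr(s1[i], 2, 2),
      substr(s2[i], 1, 1), substr(s2[i], 2, 2))
  })
  lex <- lexicon(words, freqs, phon)
  attr(lex, "syllables") <- setNames(lapply(seq_len(n_words), function(i) {
    c(s1[i], s2[i])
  }), words)
  lex
}

# consonant duration as a fraction of the syllable: varies by consonant
# identity (real consonants differ in duration), which staggers vowel
# onsets across syllables and keeps phoneme impulse trains from being
# shifted copies of the acoustic-edge trains
consonant_fraction <- function(ph_c) {
  0.24 + 0.08 * (utf8ToInt(ph_c) %% 4)
}

# deterministic synthetic syllable token: a harmonic complex whose
# fundamental depends on the vowel, with a noise burst for stop consonants
# over the consonant segment; not a speech synthesizer, but enough
# spectral/temporal structure for the gammatone and edge features
syllable_token <- function(syllable, dur_s, sample_rate) {
  ph_c <- substr(syllable, 1, 1)
  ph_v <- substr(syllable, 2, 2)
  stops <- c("p", "t", "k", "b", "d", "g")
  n <- as.integer(round(dur_s * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate

  f0 <- 100 + 15 * (utf8ToInt(ph_v) %% 7) + 3 * (utf8ToInt(ph_c) %% 5)
  n_harm <- max(1L, floor(4000 / f0))
  vow <- numeric(n)
  for (k in seq_len(n_harm)) {
    vow <- vow + sin(2 * pi * k * f0 * t + k) / k
  }
  # consonant segment: noise burst for stops, soft damped attack otherwise,
  # ending at the consonant-dependent vowel onset
  cons_n <- as.integer(round(consonant_fraction(ph_c) * n))
  attack <- exp(-t[seq_len(cons_n)] / (consonant_fraction(ph_c) * dur_s / 4))
  if (ph_c %in% stops) {
    set.seed(derive_seed(sum(utf8ToInt(syllable)), "burst"))
    vow[seq_len(cons_n)] <- vow[seq_len(cons_n)] * 0.2 +
      rnorm(cons_n) * attack * 1.5
  } else {
    vow[seq_len(cons_n)] <- vow[seq_len(cons_n)] * (1 - 0.8 * attack)
  }
  vow
}

apply_cosine_ramps <- function(x, ramp_frac) {
  n <- length(x)
  nr <- max(1L, as.integer(round(ramp_frac * n)))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[n + 1L - seq_len(nr)] <- x[n + 1L - seq_len(nr)] * ramp
  x
}

scale_to_dbfs <- function(x, level_dbfs) {
  r <- sqrt(mean(x^2))
  if (r == 0) return(x)
  x * 10^(level_dbfs / 20) / r
}

#' Synthesize isochronous stimulus streams
#'
#' Builds per-sequence audio and event streams for the four stimulus
#' conditions.  Syllable tokens are concatenated isochronously (each
#' exactly `syllable_ms` long, with 5% cosine ramps on both ends and the
#' sequence level normalised to the target dBFS); consonant onsets fall at
#' exact multiples of the syllable duration, vowel onsets at a
#' consonant-dependent fraction (24-48%) of the syllable, and word onsets
#' at even syllable indices.
#'
#' Conditions: `"words"` samples bi-syllabic words from the lexicon;
#' `"random_syllables"` permutes each words-sequence's syllable multiset
#' (identical multiset under the same seed); `"sentences"` arranges words
#' into fixed 4-word templates (one word per role class, ordered);
#' `"word_list"` shuffles the sentence words, breaking template order.
#'
#' @param lexicon A lexicon from [make_toy_lexicon()] (needs the
#'   `syllables` attribute).
#' @param condition One of `"words"`, `"random_syllables"`, `"sentences"`,
#'   `"word_list"`.
#' @param n_sequences Sequences to generate.
#' @param syllable_ms Syllable duration in ms (default 250; 200 variant).
#' @param syllables_per_sequence Syllables per sequence (default 16, i.e.
#'   8 bi-syllabic words over 4 s at 250 ms).
#' @param sample_rate Audio rate in Hz (default 16000).
#' @param ramp_frac Cosine ramp fraction per token end (default 0.05).
#' @param level_dbfs Target RMS level (default -15 dBFS).
#' @param seed Integer seed.
#' @return A list of class `"stimulus_streams"`: per sequence a list with
#'   `audio` (`audio_wave`), `events` (onset table), `syllables`, `words`;
#'   plus a `spec` attribute echoing all parameters.
#' @export
make_streams <- function(lexicon,
                         condition = c("words", "random_syllables",
                                       "sentences", "word_list"),
                         n_sequences = 12, syllable_ms = 250,
                         syllables_per_sequence = 16, sample_rate = 16000,
                         ramp_frac = 0.05, level_dbfs = -15, seed = 1) {
  condition <- match.arg(condition)
  syl_tab <- attr(lexicon, "syllables")
  if (is.null(syl_tab)) abort("Lexicon lacks a `syllables` attribute (see make_toy_lexicon).")
  n_words_seq <- syllables_per_sequence %/% 2L
  dur_s <- syllable_ms / 1000

  # word selection is seeded identically for words and random_syllables so
  # that the latter is a permutation of the former's syllable multiset
  set.seed(derive_seed(seed, "word_assignment"))
  word_seqs <- lapply(seq_len(n_sequences), function(i) {
    if (condition %in% c("sentences", "word_list")) {
      roles <- (seq_len(nrow(lexicon)) - 1L) %% 4L + 1L
      sent <- function() {
        vapply(1:4, function(r) sample(lexicon$word[roles == r], 1), character(1))
      }
      ws <- unlist(lapply(seq_len(ceiling(n_words_seq / 4)), function(.) sent()))
      ws <- ws[seq_len(n_words_seq)]
      if (condition == "word_list") ws <- sample(ws) else ws
    } else {
      sample(lexicon$word, n_words_seq, replace = TRUE)
    }
  })

  set.seed(derive_seed(seed, paste0("shuffle_", condition)))
  sequences <- lapply(seq_len(n_sequences), function(i) {
    ws <- word_seqs[[i]]
    syls <- unlist(syl_tab[ws], use.names = FALSE)
    if (condition == "random_syllables") syls <- sample(syls)

    audio <- unlist(lapply(syls, function(s) {
      apply_cosine_ramps(syllable_token(s, dur_s, sample_rate), ramp_frac)
    }), use.names = FALSE)
    audio <- scale_to_dbfs(audio, level_dbfs)

    onsets <- (seq_along(syls) - 1) * dur_s
    word_index <- (seq_along(syls) - 1L) %/% 2L + 1L
    vowel_offset <- unname(vapply(substr(syls, 1, 1), consonant_fraction,
                                  numeric(1))) * dur_s
    phon <- dplyr::bind_rows(
      tibble(onset_s = onsets, tier = "phoneme",
             label = substr(syls, 1, 1), word_index = word_index),
      tibble(onset_s = onsets + vowel_offset, tier = "phoneme",
             label = substr(syls, 2, 2), word_index = word_index)
    )
    word_onsets <- onsets[seq(1, length(syls), by = 2)]
    word_labels <- vapply(seq_along(word_onsets), function(w) {
      paste0(syls[2 * w - 1], syls[2 * w])
    }, character(1))
    events <- dplyr::arrange(dplyr::bind_rows(
      phon,
      tibble(onset_s = word_onsets, tier = "word", label = word_labels,
             word_index = seq_along(word_onsets))
    ), .data$onset_s)

    list(audio = structure(list(samples = audio, rate = sample_rate),
                           class = "audio_wave"),
         events = events, syllables = syls, words = ws)
  })

  structure(sequences, class = "stimulus_streams",
            spec = list(condition = condition, n_sequences = n_sequences,
                        syllable_ms = syllable_ms,
                        syllables_per_sequence = syllables_per_sequence,
                        sample_rate = sample_rate, ramp_frac = ramp_frac,
                        level_dbfs = level_dbfs, seed = seed))
}

#' @export
print.stimulus_streams <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<stimulus_streams> %d x %gs '%s' sequences (%d x %d ms syllables)\n",
              length(x), sp$syllables_per_sequence * sp$syllable_ms / 1000,
              sp$condition, sp$syllables_per_sequence, sp$syllable_ms))
  invisible(x)
}

#' Assemble the standard predictor set from stimulus streams
#'
#' Runs the acoustic features (gammatone and onset spectrograms) and the
#' cohort annotation over each sequence and stacks the per-sequence
#' channels into a trial-structured [predictor_set()]: families
#' `gammatone` (8), `acoustic_edges` (8), `phoneme` (onset, surprisal,
#' entropy) and optionally `word` (onset, surprisal, entropy from a
#' word-feature table).
#'
#' @param streams A `"stimulus_streams"` object.
#' @param lexicon The lexicon used for cohort statistics.
#' @param word_features Optional tibble with columns `word`,
#'   `surprisal_bits`, `entropy_bits` giving word-level values (e.g. from
#'   an external language model); when supplied, `word` family channels
#'   are built.
#' @param rate Predictor grid rate in Hz (default 100).
#' @param n_bands,fmin,fmax Filterbank parameters (defaults 8, 20, 5000).
#' @param fallback,include_word_end Passed to [annotate_events()].
#' @return A `"predictor_set"` (unnormalised, unpadded), one trial per
#'   sequence.
#' @export
build_predictors <- function(streams, lexicon, word_features = NULL,
                             rate = 100, n_bands = 8, fmin = 20, fmax = 5000,
                             fallback = "uniform", include_word_end = TRUE) {
  stopifnot(inherits(streams, "stimulus_streams"))
  per_trial <- lapply(streams, function(sq) {
    env <- gammatone_spectrogram(sq$audio, n_bands = n_bands, fmin = fmin,
                                 fmax = fmax, out_rate = rate)
    ons <- onset_spectrogram(env)
    n_frames <- nrow(env$values)
    ann <- annotate_events(sq$events, lexicon, fallback = fallback,
                           include_word_end = include_word_end, quiet = TRUE)
    ph_on <- events_to_impulses(ann, n_frames, rate)
    ph_sur <- events_to_impulses(ann, n_frames, rate, value = "surprisal_bits")
    ph_ent <- events_to_impulses(ann, n_frames, rate, value = "entropy_bits")
    m <- cbind(env$values, ons$values, ph_on, ph_sur, ph_ent)
    colnames(m) <- c(sprintf("gammatone_%d", seq_len(n_bands)),
                     sprintf("edge_%d", seq_len(n_bands)),
                     "phoneme_onset", "phoneme_surprisal", "phoneme_entropy")
    fams <- c(rep("gammatone", n_bands), rep("acoustic_edges", n_bands),
              rep("phoneme", 3))
    if (!is.null(word_features)) {
      wev <- sq$events[sq$events$tier == "word", , drop = FALSE]
      wev <- dplyr::left_join(wev, word_features, by = c("label" = "word"))
      wev$surprisal_bits[is.na(wev$surprisal_bits)] <-
        mean(word_features$surprisal_bits)
      wev$entropy_bits[is.na(wev$entropy_bits)] <-
        mean(word_features$entropy_bits)
      w_on <- events_to_impulses(wev, n_frames, rate)
      w_sur <- events_to_impulses(wev, n_frames, rate, value = "surprisal_bits")
      w_ent <- events_to_impulses(wev, n_frames, rate, value = "entropy_bits")
      m <- cbind(m, word_onset = w_on, word_surprisal = w_sur,
                 word_entropy = w_ent)
      fams <- c(fams, rep("word", 3))
    }
    list(m = m, fams = fams)
  })
  mats <- lapply(per_trial, `[[`, "m")
  lens <- vapply(mats, nrow, integer(1))
  ends <- cumsum(lens)
  predictor_set(do.call(rbind, mats), per_trial[[1]]$fams, rate = rate,
                trials = tibble(trial = seq_along(mats),
                                start = ends - lens + 1L, end = ends))
}

#' Word-level feature table from a lexicon
#'
#' Unigram stand-in for language-model word statistics: surprisal is
#' \eqn{-\log_2} of relative frequency; entropy values are drawn from a
#' seeded normal (mean 3 bits, sd 1, truncated at 0), emulating the spread
#' of next-word entropy estimates.
#'
#' @param lexicon A [lexicon()].
#' @param seed Integer seed.
#' @return A tibble with `word`, `surprisal_bits`, `entropy_bits`.
#' @export
unigram_word_features <- function(lexicon, seed = 1) {
  set.seed(derive_seed(seed, "word_features"))
  tibble(
    word = lexicon$word,
    surprisal_bits = -log2(lexicon$frequency / attr(lexicon, "total_frequency")),
    entropy_bits = pmax(0, rnorm(nrow(lexicon), 3, 1))
  )
}

#' Ground-truth TRF kernels with condition modulation
#'
#' Defines, per feature family, a kernel as a gamma-density bump on the
#' lag axis (zero at negative lags), with per-channel amplitude variation
#' and multiplicative condition modulation factors restricted to a lag
#' window.  Defaults place the acoustic bump near 100 ms and the phoneme
#' bump near 400 ms.
#'
#' @param cols Design column table (`channel`, `family`, `lag_ms`) from a
#'   `"lag_design"`.
#' @param family_spec Named list: per family, `list(peak_ms=, amplitude=)`.
#'   Families absent from the list get zero kernels.
#' @param modulation Tibble with columns `family`, `condition`, `factor`,
#'   and optionally `window_lo_ms`, `window_hi_ms` (defaults: whole axis).
#' @param seed Integer seed (per-channel amplitude draw).
#' @return A list of class `"ground_truth"` with `base` (named base kernel
#'   vector over design columns), `cols`, `family_spec`, `modulation`.
#' @export
ground_truth <- function(cols,
                         family_spec = list(
                           gammatone = list(peak_ms = 80, amplitude = 0.3),
                           acoustic_edges = list(peak_ms = 100, amplitude = 1),
                           phoneme = list(peak_ms = 400, amplitude = 1)
                         ),
                         modulation = NULL, seed = 1) {
  set.seed(derive_seed(seed, "truth_channels"))
  base <- numeric(nrow(cols))
  for (ch in unique(cols$channel)) {
    rows <- which(cols$channel == ch)
    fam <- cols$family[rows[1]]
    fs <- family_spec[[fam]]
    if (is.null(fs)) next
    amp <- fs$amplitude * runif(1, 0.6, 1.4)
    base[rows] <- amp * gamma_bump(cols$lag_ms[rows], fs$peak_ms)
  }
  structure(list(base = base, cols = cols, family_spec = family_spec,
                 modulation = modulation, seed = seed),
            class = "ground_truth")
}

# gamma-density bump over lag (ms), unit peak, zero for lag <= 0
gamma_bump <- function(lag_ms, peak_ms, shape = 4) {
  scale <- peak_ms / (shape - 1)
  v <- ifelse(lag_ms > 0, stats::dgamma(lag_ms, shape = shape, scale = scale), 0)
  pk <- stats::dgamma(peak_ms, shape = shape, scale = scale)
  v / pk
}

#' Condition-specific kernel from a ground truth
#'
#' Applies the multiplicative condition modulation factors (within their
#' lag windows) to the base kernel.
#'
#' @param truth A `"ground_truth"`.
#' @param condition Condition name.
#' @return Numeric kernel vector over the design columns.
#' @export
truth_kernel <- function(truth, condition) {
  k <- truth$base
  mod <- truth$modulation
  if (is.null(mod)) return(k)
  mod <- mod[mod$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(mod))) {
    lo <- if ("window_lo_ms" %in% names(mod) && is.finite(mod$window_lo_ms[i])) {
      mod$window_lo_ms[i]
    } else -Inf
    hi <- if ("window_hi_ms" %in% names(mod) && is.finite(mod$window_hi_ms[i])) {
      mod$window_hi_ms[i]
    } else Inf
    rows <- truth$cols$family == mod$family[i] &
      truth$cols$lag_ms >= lo & truth$cols$lag_ms <= hi
    k[rows] <- k[rows] * mod$factor[i]
  }
  k
}

#' Simulate multi-subject source responses from a forward model
#'
#' Per subject and source, the response is the forward model
#' \eqn{y = \sum_f \beta_f * x_f} evaluated on the lagged design, scaled by
#' a per-source gain and a per-subject amplitude jitter, plus white
#' Gaussian noise with \eqn{var(signal)/var(noise) = } `snr`.
#'
#' @param design A `"lag_design"` (normalised, padded predictors).
#' @param truth A `"ground_truth"`.
#' @param condition Condition name (selects the modulation).
#' @param n_subjects,n_sources Counts (defaults 15 and 4).
#' @param snr Signal-to-noise variance ratio (default 0.5); `Inf` disables
#'   noise.
#' @param jitter_sd Per-subject multiplicative amplitude jitter sd
#'   (default 0.1).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of `"source_response"` objects, one per subject.
#' @export
simulate_responses <- function(design, truth, condition = "default",
                               n_subjects = 15, n_sources = 4, snr = 0.5,
                               jitter_sd = 0.1, seed = 1) {
  stopifnot(inherits(design, "lag_design"), inherits(truth, "ground_truth"))
  kern <- truth_kernel(truth, condition)
  clean <- drop(design$X %*% kern)
  set.seed(derive_seed(seed, paste0("sim_", condition)))
  gains <- runif(n_sources, 0.6, 1.4)
  jitter <- pmax(0.2, rnorm(n_subjects, 1, jitter_sd))
  sd_clean <- sd(clean)

  lapply(seq_len(n_subjects), function(si) {
    vals <- vapply(seq_len(n_sources), function(so) {
      y <- clean * gains[so] * jitter[si]
      if (is.finite(snr)) {
        y <- y + rnorm(length(y), 0, sd_clean * gains[so] * jitter[si] / sqrt(snr))
      }
      y
    }, numeric(length(clean)))
    colnames(vals) <- paste0("source", seq_len(n_sources))
    source_response(vals, rate = design$rate, trials = design$trials,
                    support = design$support)
  })
}

#' Build a complete synthetic experiment bundle
#'
#' Generates a toy lexicon, per-subject stimulus streams for a
#' two-condition contrast (each subject gets an independent random stream
#' sampling, as in experiments that randomise stimulus selection per
#' participant; in the familiarity contrast both conditions share the
#' subject's streams), the standard predictor sets (normalised, padded),
#' a ground truth with the preset's injected effect, and simulated
#' multi-subject responses, together with a manifest echoing every
#' parameter and seed.  Per-subject source gains and amplitude jitter are
#' drawn once per subject and held fixed across conditions.  Lag designs
#' are deliberately not stored (they are large); [run_fit()] rebuilds them
#' deterministically from the stored predictor sets.
#'
#' Presets and their injected effects:
#' \describe{
#'   \item{`words_vs_syllables`}{words vs random-syllable streams; phoneme
#'     kernel amplitude x1.5 in the words condition.}
#'   \item{`sentences_vs_wordlist`}{sentence vs shuffled word-list streams
#'     (with word-level features); phoneme kernel x1.3 in sentences.}
#'   \item{`familiarity`}{word streams heard as "native" vs "unfamiliar";
#'     acoustic-edge kernel x1.3 in the unfamiliar condition over the
#'     early window (-50 to 150 ms).}
#'   \item{`null`}{words vs random syllables with all modulation factors 1.}
#' }
#'
#' @param preset One of `"words_vs_syllables"`, `"sentences_vs_wordlist"`,
#'   `"familiarity"`, `"null"`.
#' @param seed Integer seed.
#' @param n_subjects,n_sources,n_sequences,snr Simulation scale (defaults
#'   15 subjects, 4 sources, 8 sequences per condition, SNR 0.5).
#' @param syllable_ms,syllables_per_sequence Stimulus timing (defaults 250
#'   and 16).
#' @param sample_rate Audio rate (default 16000 Hz).
#' @param jitter_sd Per-subject amplitude jitter sd (default 0.1).
#' @return A list of class `"trf_experiment"`: `lexicon`, `conditions`
#'   (names), `streams` and `predictors` (per condition: one entry per
#'   subject), `responses` (per condition: per-subject source responses),
#'   `truth`, `manifest`.
#' @export
make_experiment <- function(preset = c("words_vs_syllables",
                                       "sentences_vs_wordlist",
                                       "familiarity", "null"),
                            seed = 1, n_subjects = 15, n_sources = 4,
                            n_sequences = 8, snr = 0.5, syllable_ms = 250,
                            syllables_per_sequence = 16, sample_rate = 16000,
                            jitter_sd = 0.1) {
  preset <- match.arg(preset)
  lex <- make_toy_lexicon(seed = seed)

  cfg <- switch(preset,
    words_vs_syllables = list(
      conditions = c("words", "random_syllables"),
      stream_cond = c("words", "random_syllables"),
      word_features = FALSE,
      modulation = tibble(family = "phoneme", condition = "words",
                          factor = 1.5,
                          window_lo_ms = -Inf, window_hi_ms = Inf)
    ),
    sentences_vs_wordlist = list(
      conditions = c("sentences", "word_list"),
      stream_cond = c("sentences", "word_list"),
      word_features = TRUE,
      modulation = tibble(family = "phoneme", condition = "sentences",
                          factor = 1.3,
                          window_lo_ms = -Inf, window_hi_ms = Inf)
    ),
    familiarity = list(
      conditions = c("native", "unfamiliar"),
      stream_cond = c("words", "words"),
      word_features = FALSE,
      modulation = tibble(family = "acoustic_edges",
                          condition = "unfamiliar", factor = 1.3,
                          window_lo_ms = -50, window_hi_ms = 150)
    ),
    null = list(
      conditions = c("words", "random_syllables"),
      stream_cond = c("words", "random_syllables"),
      word_features = FALSE,
      modulation = NULL
    )
  )

  wf <- if (cfg$word_features) unigram_word_features(lex, seed = seed) else NULL

  # per-subject amplitude structure, fixed across conditions
  set.seed(derive_seed(seed, "subject_amplitudes"))
  gains <- matrix(runif(n_subjects * n_sources, 0.6, 1.4),
                  nrow = n_subjects)
  jitter <- pmax(0.2, rnorm(n_subjects, 1, jitter_sd))

  streams <- predictors <- responses <- list()
  truth <- NULL
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[ci]
    streams[[cond]] <- vector("list", n_subjects)
    predictors[[cond]] <- vector("list", n_subjects)
    responses[[cond]] <- vector("list", n_subjects)
    for (si in seq_len(n_subjects)) {
      st <- make_streams(lex, condition = cfg$stream_cond[ci],
                         n_sequences = n_sequences,
                         syllable_ms = syllable_ms,
                         syllables_per_sequence = syllables_per_sequence,
                         sample_rate = sample_rate,
                         seed = derive_seed(seed, paste0("subj", si)))
      ps <- build_predictors(st, lex, word_features = wf)
      ps <- normalize_channels(ps)
      ps <- pad_trials(ps)
      des <- lag_expand(ps)
      if (is.null(truth)) {
        fams <- list(
          gammatone = list(peak_ms = 80, amplitude = 0.3),
          acoustic_edges = list(peak_ms = 100, amplitude = 1),
          phoneme = list(peak_ms = 400, amplitude = 1)
        )
        truth <- ground_truth(des$cols, family_spec = fams,
                              modulation = cfg$modulation, seed = seed)
      }
      kern <- truth_kernel(truth, cond)
      clean <- drop(des$X %*% kern) * jitter[si]
      set.seed(derive_seed(seed, paste0("noise_", cond, "_", si)))
      vals <- vapply(seq_len(n_sources), function(so) {
        y <- clean * gains[si, so]
        if (is.finite(snr)) {
          y <- y + rnorm(length(y), 0, sd(y) / sqrt(snr))
        }
        y
      }, numeric(length(clean)))
      colnames(vals) <- paste0("source", seq_len(n_sources))
      resp <- source_response(vals, rate = des$rate, trials = des$trials,
                              support = des$support)
      streams[[cond]][[si]] <- st
      predictors[[cond]][[si]] <- ps
      responses[[cond]][[si]] <- normalize_channels(resp)
    }
  }

  manifest <- list(
    preset = preset, seed = seed,
    conditions = as.list(cfg$conditions),
    n_subjects = n_subjects, n_sources = n_sources,
    n_sequences = n_sequences, snr = snr, jitter_sd = jitter_sd,
    syllable_ms = syllable_ms,
    syllables_per_sequence = syllables_per_sequence,
    sample_rate = sample_rate,
    ramp_frac = 0.05, level_dbfs = -15,
    truth = list(
      family_peaks_ms = lapply(truth$family_spec, `[[`, "peak_ms"),
      family_amplitudes = lapply(truth$family_spec, `[[`, "amplitude"),
      modulation = if (is.null(cfg$modulation)) list() else
        lapply(seq_len(nrow(cfg$modulation)), function(i) as.list(cfg$modulation[i, ]))
    )
  )

  structure(list(lexicon = lex, conditions = cfg$conditions,
                 streams = streams, predictors = predictors,
                 responses = responses, truth = truth,
                 manifest = manifest),
            class = "trf_experiment")
}

#' @export
print.trf_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<trf_experiment:%s> %s | %d subjects, %d sources, %d sequences/cond, SNR %g\n",
              m$preset, paste(x$conditions, collapse = " vs "),
              m$n_subjects, m$n_sources, m$n_sequences, m$snr))
  invisible(x)
}
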