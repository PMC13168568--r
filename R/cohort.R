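#' Incremental cohort statistics
#'
#' The cohort model of spoken-word recognition tracks, phoneme by phoneme,
#' the set of lexical candidates consistent with the input so far.  The
#' conditional probability of a phoneme is the frequency mass of the cohort
#' that survives it, divided by the mass of the previous cohort; surprisal
#' is \eqn{-\log_2} of that probability, and entropy is the Shannon entropy
#' (bits) of the frequency-weighted distribution over possible next
#' phonemes.
#'
#' `cohort_init()` creates the word-initial state (the full lexicon).
#' `advance_cohort()` consumes one phoneme and returns the new state
#' together with the conditional probability of that phoneme.  When a
#' phoneme empties the cohort (guaranteed for pseudoword streams), a
#' fallback policy applies: `"uniform"` (the default) scores the phoneme
#' with probability `1/|inventory|` and leaves the cohort empty;
#' `"restart"` re-enters the full lexicon as if word-initial before
#' consuming the phoneme.  Fallback steps are flagged.
#'
#' @param lexicon A [lexicon()] object.
#' @param state A cohort state from `cohort_init()` or `advance_cohort()`.
#' @param phoneme A single phoneme symbol (must be in the lexicon inventory).
#' @param fallback `"uniform"` or `"restart"`.
#'
#' @return `cohort_init()`: a `cohort_state` (list with `prefix`, `members`,
#'   `mass`, `fallback`).  `advance_cohort()`: a list with elements `state`,
#'   `probability`, and `fallback`.
#' @export
#' @examples
#' lex <- lexicon(c("ba", "bi", "da"), c(2, 1, 1),
#'                list(c("b", "a"), c("b", "i"), c("d", "a")))
#' st <- cohort_init(lex)
#' advance_cohort(lex, st, "b")$probability  # 3/4
cohort_init <- function(lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  structure(
    list(prefix = character(0), members = seq_len(nrow(lexicon)),
         mass = attr(lexicon, "total_frequency"), fallback = FALSE),
    class = "cohort_state"
  )
}

#' @rdname cohort_init
#' @export
advance_cohort <- function(lexicon, state, phoneme,
                           fallback = c("uniform", "restart")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(lexicon, "lexicon"), inherits(state, "cohort_state"))
  inventory <- attr(lexicon, "inventory")
  if (!is.character(phoneme) || length(phoneme) != 1L) {
    abort("`phoneme` must be a single symbol.")
  }
  if (!phoneme %in% inventory) {
    abort(sprintf("Phoneme '%s' is not in the lexicon inventory.", phoneme))
  }

  pos <- length(state$prefix) + 1L
  survivors <- state$members[vapply(
    lexicon$phonemes[state$members],
    function(p) length(p) >= pos && p[[pos]] == phoneme,
    logical(1)
  )]
  new_mass <- sum(lexicon$frequency[survivors])

  if (length(survivors) > 0L && !state$fallback) {
    new_state <- structure(
      list(prefix = c(state$prefix, phoneme), members = survivors,
           mass = new_mass, fallback = FALSE),
      class = "cohort_state"
    )
    return(list(state = new_state, probability = new_mass / state$mass,
                fallback = FALSE))
  }

  if (fallback == "restart") {
    restarted <- which(vapply(lexicon$phonemes,
                              function(p) length(p) >= 1L && p[[1L]] == phoneme,
                              logical(1)))
    if (length(restarted) > 0L) {
      mass <- sum(lexicon$frequency[restarted])
      new_state <- structure(
        list(prefix = phoneme, members = restarted, mass = mass,
             fallback = FALSE),
        class = "cohort_state"
      )
      return(list(state = new_state,
                  probability = mass / attr(lexicon, "total_frequency"),
                  fallback = TRUE))
    }
  }

  # uniform fallback: cohort stays empty, phoneme scored uniformly
  new_state <- structure(
    list(prefix = c(state$prefix, phoneme), members = integer(0),
         mass = 0, fallback = TRUE),
    class = "cohort_state"
  )
  list(state = new_state, probability = 1 / length(inventory), fallback = TRUE)
}

#' Entropy of the next-phoneme distribution
#'
#' Shannon entropy, in bits, of the frequency-weighted distribution over
#' possible continuations of the current cohort.  When a cohort member's
#' phoneme sequence is exhausted by the prefix, its mass is assigned to a
#' terminal "word ends here" outcome if `include_word_end = TRUE` (the
#' default, which keeps the distribution proper when words are prefixes of
#' longer words); with `include_word_end = FALSE` exhausted members are
#' dropped and the distribution renormalised over continuing members.
#'
#' @inheritParams cohort_init
#' @param include_word_end Include the terminal outcome (default `TRUE`).
#' @return Entropy in bits (a single non-negative number).
#' @export
next_phoneme_entropy <- function(lexicon, state, include_word_end = TRUE) {
  stopifnot(inherits(lexicon, "lexicon"), inherits(state, "cohort_state"))
  if (state$mass <= 0 || length(state$members) == 0L) {
    abort("Cohort state has zero mass; apply the fallback policy instead.")
  }
  pos <- length(state$prefix) + 1L
  seqs <- lexicon$phonemes[state$members]
  freqs <- lexicon$frequency[state$members]
  nxt <- vapply(seqs, function(p) if (length(p) >= pos) p[[pos]] else "#",
                character(1))
  if (!include_word_end) {
    keep <- nxt != "#"
    if (!any(keep)) return(0)
    nxt <- nxt[keep]
    freqs <- freqs[keep]
  }
  mass <- tapply(freqs, nxt, sum)
  p <- as.numeric(mass) / sum(freqs)
  -sum(p * log2(p))
}

#' Per-phoneme cohort statistics for one word
#'
#' Runs the cohort from the word-initial state through the given phoneme
#' sequence, recording at each position the conditional probability,
#' surprisal (bits), next-phoneme entropy (bits) and whether the fallback
#' policy fired.
#'
#' @inheritParams cohort_init
#' @param word Character vector: the word's phoneme sequence.
#' @param include_word_end Passed to [next_phoneme_entropy()].
#' @param condition_entropy_on `"after"` (default): entropy of the next
#'   phoneme given the cohort after consuming phoneme *i*; `"before"`:
#'   entropy of phoneme *i* itself given the previous cohort.
#' @return A tibble with columns `position`, `phoneme`, `probability`,
#'   `surprisal_bits`, `entropy_bits`, `fallback`.
#' @export
#' @examples
#' lex <- lexicon(c("ba", "bi", "da"), c(2, 1, 1),
#'                list(c("b", "a"), c("b", "i"), c("d", "a")))
#' word_surprisal_profile(lex, c("b", "a"))
word_surprisal_profile <- function(lexicon, word,
                                   fallback = c("uniform", "restart"),
                                   include_word_end = TRUE,
                                   condition_entropy_on = c("after", "before")) {
  fallback <- match.arg(fallback)
  condition_entropy_on <- match.arg(condition_entropy_on)
  if (length(word) == 0L) abort("`word` must be a non-empty phoneme sequence.")
  inventory <- attr(lexicon, "inventory")
  uniform_entropy <- log2(length(inventory))

  state <- cohort_init(lexicon)
  n <- length(word)
  probability <- surprisal <- entropy <- numeric(n)
  fell <- logical(n)
  for (i in seq_len(n)) {
    before <- state
    step <- advance_cohort(lexicon, state, word[[i]], fallback = fallback)
    probability[i] <- step$probability
    surprisal[i] <- -log2(step$probability)
    fell[i] <- step$fallback
    ref <- if (condition_entropy_on == "after") step$state else before
    entropy[i] <- if (ref$mass > 0 && length(ref$members) > 0L) {
      next_phoneme_entropy(lexicon, ref, include_word_end = include_word_end)
    } else {
      uniform_entropy
    }
    state <- step$state
  }
  tibble(position = seq_len(n), phoneme = as.character(word),
         probability = probability, surprisal_bits = surprisal,
         entropy_bits = entropy, fallback = fell)
}

#' Annotate a phoneme segmentation with cohort statistics
#'
#' Joins a phoneme/word segmentation with a lexicon: each phoneme event
#' receives an onset indicator, its cohort surprisal and entropy, and a
#' fallback flag.  The cohort resets at every word onset (words are
#' identified by `word_index`).
#'
#' @param events A tibble with columns `onset_s`, `tier` (`"phoneme"` or
#'   `"word"`), `label`, `word_index`.  Only phoneme rows are annotated.
#' @inheritParams word_surprisal_profile
#' @param quiet Suppress the fallback-count message.
#' @return A tibble with columns `onset_s`, `phoneme`, `word_index`,
#'   `onset_flag`, `surprisal_bits`, `entropy_bits`, `fallback`, ordered by
#'   onset time.
#' @export
annotate_events <- function(events, lexicon,
                            fallback = c("uniform", "restart"),
                            include_word_end = TRUE,
                            condition_entropy_on = c("after", "before"),
                            quiet = FALSE) {
  fallback <- match.arg(fallback)
  condition_entropy_on <- match.arg(condition_entropy_on)
  stopifnot(is.data.frame(events))
  needed <- c("onset_s", "tier", "label", "word_index")
  if (!all(needed %in% names(events))) {
    abort(sprintf("`events` must have columns %s.", paste(needed, collapse = ", ")))
  }
  ph <- events[events$tier == "phoneme", , drop = FALSE]
  if (nrow(ph) == 0L) {
    return(tibble(onset_s = numeric(0), phoneme = character(0),
                  word_index = integer(0), onset_flag = numeric(0),
                  surprisal_bits = numeric(0), entropy_bits = numeric(0),
                  fallback = logical(0)))
  }
  ph <- ph[order(ph$word_index, ph$onset_s), , drop = FALSE]
  out <- dplyr::group_modify(
    dplyr::group_by(ph, .data$word_index),
    function(d, key) {
      prof <- word_surprisal_profile(
        lexicon, d$label, fallback = fallback,
        include_word_end = include_word_end,
        condition_entropy_on = condition_entropy_on
      )
      tibble(onset_s = d$onset_s, phoneme = d$label, onset_flag = 1,
             surprisal_bits = prof$surprisal_bits,
             entropy_bits = prof$entropy_bits, fallback = prof$fallback)
    }
  )
  out <- dplyr::ungroup(out)
  out <- out[order(out$onset_s),
             c("onset_s", "phoneme", "word_index", "onset_flag",
               "surprisal_bits", "entropy_bits", "fallback")]
  n_fallback <- sum(out$fallback)
  if (n_fallback > 0 && !quiet) {
    rlang::inform(sprintf("Cohort fallback applied to %d of %d phoneme events.",
                          n_fallback, nrow(out)))
  }
  out
}
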