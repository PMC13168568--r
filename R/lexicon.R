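#' Construct a frequency-weighted pronunciation lexicon
#'
#' A lexicon is the universe over which incremental cohort statistics are
#' computed: one row per orthographic word form, with its occurrence
#' frequency and phoneme sequence.  Duplicate forms are merged by summing
#' frequencies; forms containing any non-letter character are dropped, and
#' records with non-positive frequency are rejected with a warning.
#'
#' @param word Character vector of orthographic forms.
#' @param frequency Numeric vector of positive occurrence counts.
#' @param phonemes List of character vectors, one phoneme sequence per word.
#' @param case Either `"fold"` (lower-case forms before filtering/merging,
#'   the default) or `"preserve"`.
#'
#' @return A tibble of class `"lexicon"` with columns `word`, `frequency`,
#'   `phonemes` (list column), and attributes `inventory` (the phoneme
#'   alphabet of surviving entries) and `total_frequency`.
#' @export
#' @examples
#' lex <- lexicon(c("ba", "bi", "da"), c(2, 1, 1),
#'                list(c("b", "a"), c("b", "i"), c("d", "a")))
#' attr(lex, "total_frequency")
lexicon <- function(word, frequency, phonemes, case = c("fold", "preserve")) {
  case <- match.arg(case)
  if (length(word) != length(frequency) || length(word) != length(phonemes)) {
    abort("`word`, `frequency` and `phonemes` must have equal length.")
  }
  if (case == "fold") word <- tolower(word)

  bad_freq <- !is.finite(frequency) | frequency <= 0
  if (any(bad_freq)) {
    warn(sprintf("Rejected %d record(s) with non-positive frequency.", sum(bad_freq)))
  }
  keep <- is_alphabetic(word) & !bad_freq
  word <- word[keep]
  frequency <- frequency[keep]
  phonemes <- phonemes[keep]
  if (length(word) == 0L) {
    abort("Lexicon is empty after filtering non-alphabetic forms.")
  }

  # merge duplicate forms by summing frequency; first pronunciation wins
  if (anyDuplicated(word)) {
    first <- !duplicated(word)
    merged_freq <- tapply(frequency, word, sum)
    word_u <- word[first]
    frequency <- as.numeric(merged_freq[word_u])
    phonemes <- phonemes[first]
    word <- word_u
  }

  phonemes <- lapply(phonemes, as.character)
  out <- tibble(word = word, frequency = as.numeric(frequency), phonemes = phonemes)
  attr(out, "inventory") <- sort(unique(unlist(phonemes)))
  attr(out, "total_frequency") <- sum(out$frequency)
  class(out) <- c("lexicon", class(out))
  out
}

#' Read a lexicon from a tab-separated file
#'
#' Expects UTF-8 TSV with columns `word`, `frequency`, `phonemes`
#' (space-separated phoneme symbols); lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @inheritParams lexicon
#' @return A [lexicon()] object.
#' @export
read_lexicon <- function(path, case = c("fold", "preserve")) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          word = readr::col_character(),
                          frequency = readr::col_double(),
                          phonemes = readr::col_character()
                        ))
  if (nrow(df) == 0L) abort("Lexicon file has no records.")
  lexicon(df$word, df$frequency, strsplit(df$phonemes, "\\s+"), case = case)
}

#' Write a lexicon to a tab-separated file
#'
#' @param lex A [lexicon()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  df <- tibble(
    word = lex$word,
    frequency = lex$frequency,
    phonemes = vapply(lex$phonemes, paste, character(1), collapse = " ")
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d entries, %d phonemes, total frequency %g\n",
              nrow(x), length(attr(x, "inventory")), attr(x, "total_frequency")))
  NextMethod()
}
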