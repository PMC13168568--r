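# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# all characters are Unicode letters (covers Turkish dotted/dotless i, CJK)
is_alphabetic <- function(x) {
  grepl("^\\p{L}+$", x, perl = TRUE)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# frame index (1-based) of a continuous onset time at a given rate; events are
# binned into the frame whose interval [k, k+1)/rate contains them
frame_of <- function(onset_s, rate) {
  as.integer(floor(onset_s * rate + 1e-9)) + 1L
}

# deterministic child seed derived from a parent seed and a stream label,
# kept below 2^31
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}
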