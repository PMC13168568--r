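#' Impulse-code events onto the predictor grid
#'
#' Places each event's value at the frame containing its onset (frame `k`
#' covers `[k, k+1)/rate` seconds); events sharing a frame sum.  With
#' `value = NULL` each event contributes 1 (an onset indicator).
#'
#' @param events Tibble with column `onset_s`, plus the value column if
#'   `value` is given.
#' @param n_frames Grid length in frames.
#' @param rate Grid rate in Hz (default 100).
#' @param value Name of the column holding event values, or `NULL`.
#' @return Numeric vector of length `n_frames`.
#' @export
#' @examples
#' ev <- tibble::tibble(onset_s = 0.5, surprisal_bits = 2)
#' events_to_impulses(ev, 100, value = "surprisal_bits")[51]
events_to_impulses <- function(events, n_frames, rate = 100, value = NULL) {
  x <- numeric(n_frames)
  if (nrow(events) == 0L) return(x)
  idx <- frame_of(events$onset_s, rate)
  if (any(idx < 1L | idx > n_frames)) {
    bad <- events$onset_s[idx < 1L | idx > n_frames]
    abort(sprintf("Event(s) outside the grid at onset %s s.",
                  paste(signif(bad, 6), collapse = ", ")))
  }
  v <- if (is.null(value)) rep(1, nrow(events)) else events[[value]]
  for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + v[i]
  x
}

#' Trial-structured predictor set
#'
#' A named multichannel regressor time series on a uniform grid, with
#' channels grouped into feature families and trials marked as contiguous
#' sample ranges.  `support` marks real (unpadded) samples; normalisation
#' statistics are computed over the support only.
#'
#' @param channels Numeric matrix, samples x channels.
#' @param families Character vector, one family tag per channel (e.g.
#'   `"gammatone"`, `"acoustic_edges"`, `"phoneme"`, `"word"`).
#' @param rate Grid rate in Hz.
#' @param trials Tibble with columns `trial`, `start`, `end` (row ranges).
#' @param support Logical vector marking unpadded samples (default all).
#' @return A list of class `"predictor_set"`.
#' @export
predictor_set <- function(channels, families, rate = 100, trials = NULL,
                          support = NULL) {
  channels <- as.matrix(channels)
  if (is.null(colnames(channels))) {
    colnames(channels) <- paste0("ch", seq_len(ncol(channels)))
  }
  if (length(families) != ncol(channels)) {
    abort("`families` must have one tag per channel.")
  }
  if (is.null(trials)) {
    trials <- tibble(trial = 1L, start = 1L, end = nrow(channels))
  }
  if (is.null(support)) support <- rep(TRUE, nrow(channels))
  structure(
    list(channels = channels, families = as.character(families), rate = rate,
         trials = trials, support = support, normalization = NULL),
    class = "predictor_set"
  )
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("<predictor_set> %d samples x %d channels @ %g Hz, %d trial(s)%s\n",
              nrow(x$channels), ncol(x$channels), x$rate, nrow(x$trials),
              if (!is.null(x$normalization)) ", normalized" else ""))
  cat("  families:", paste(unique(x$families), collapse = ", "), "\n")
  invisible(x)
}

#' Multi-source response container
#'
#' Source-level neural time series sharing the predictor grid and trial
#' structure (simulated or imported).
#'
#' @param values Numeric matrix, samples x sources.
#' @param rate Grid rate in Hz.
#' @param trials Trial table as in [predictor_set()].
#' @param support Logical unpadded-sample mask.
#' @return A list of class `"source_response"`.
#' @export
source_response <- function(values, rate = 100, trials = NULL, support = NULL) {
  values <- as.matrix(values)
  if (is.null(trials)) trials <- tibble(trial = 1L, start = 1L, end = nrow(values))
  if (is.null(support)) support <- rep(TRUE, nrow(values))
  structure(list(values = values, rate = rate, trials = trials,
                 support = support, normalization = NULL),
            class = "source_response")
}

z_score_columns <- function(m, support) {
  mu <- colMeans(m[support, , drop = FALSE])
  sigma <- apply(m[support, , drop = FALSE], 2, sd)
  if (any(sigma == 0 | !is.finite(sigma))) {
    bad <- colnames(m)[sigma == 0 | !is.finite(sigma)]
    abort(sprintf("Zero-variance channel(s): %s.",
                  paste(bad %||% which(sigma == 0), collapse = ", ")))
  }
  list(values = sweep(sweep(m, 2, mu), 2, sigma, "/"),
       stats = tibble(channel = colnames(m) %||% as.character(seq_along(mu)),
                      mean = mu, sd = sigma))
}

#' Z-score predictor channels or response sources
#'
#' Subtracts the mean and divides by the standard deviation per channel
#' (or source).  Statistics are computed over the unpadded support only and
#' applied everywhere; the `(mean, sd)` pairs are recorded on the object
#' for inverse transforms.
#'
#' @param x A `"predictor_set"` or `"source_response"`.
#' @return The same class of object, normalised.
#' @export
normalize_channels <- function(x) {
  UseMethod("normalize_channels")
}

#' @export
normalize_channels.predictor_set <- function(x) {
  z <- z_score_columns(x$channels, x$support)
  x$channels <- z$values
  x$channels[!x$support, ] <- 0  # padding stays exactly zero
  x$normalization <- z$stats
  x
}

#' @export
normalize_channels.source_response <- function(x) {
  z <- z_score_columns(x$values, x$support)
  x$values <- z$values
  x$normalization <- z$stats
  x
}

#' Zero-pad trials for the lag window
#'
#' Extends every trial with zero frames covering 50 ms before its onset and
#' 700 ms after its offset, so that lagged regressors near trial edges do
#' not wrap or truncate.  Padded samples are marked off-support.  When a
#' response is supplied its trials are padded identically (with zeros).
#'
#' @param set A `"predictor_set"` (normalise first: padding must stay zero).
#' @param response Optional `"source_response"` on the same grid.
#' @param pre_s,post_s Padding durations in seconds (defaults 0.05 and 0.7).
#' @return The padded `"predictor_set"`, or a list
#'   `list(predictors, response)` when `response` is given.
#' @export
pad_trials <- function(set, response = NULL, pre_s = 0.05, post_s = 0.7) {
  stopifnot(inherits(set, "predictor_set"))
  pre <- as.integer(round(pre_s * set$rate))
  post <- as.integer(round(post_s * set$rate))
  if (any(set$trials$end < set$trials$start)) abort("Zero-length trial.")
  if (!is.null(response)) {
    if (nrow(response$values) != nrow(set$channels)) {
      abort("Predictors and response have misaligned lengths.")
    }
  }

  pad_mat <- function(m) {
    blocks <- lapply(seq_len(nrow(set$trials)), function(i) {
      r <- set$trials$start[i]:set$trials$end[i]
      rbind(matrix(0, pre, ncol(m)), m[r, , drop = FALSE],
            matrix(0, post, ncol(m)))
    })
    do.call(rbind, blocks)
  }
  lens <- set$trials$end - set$trials$start + 1L
  new_lens <- lens + pre + post
  new_end <- cumsum(new_lens)
  new_trials <- tibble(trial = set$trials$trial,
                       start = new_end - new_lens + 1L, end = new_end)
  supp <- unlist(lapply(lens, function(n) {
    c(rep(FALSE, pre), rep(TRUE, n), rep(FALSE, post))
  }))

  out <- set
  out$channels <- pad_mat(set$channels)
  out$trials <- new_trials
  out$support <- supp
  if (is.null(response)) return(out)

  resp <- response
  resp$values <- pad_mat(response$values)
  resp$trials <- new_trials
  resp$support <- supp
  list(predictors = out, response = resp)
}

#' Export predictor channels as TSV
#'
#' @param set A `"predictor_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictors_tsv <- function(set, path) {
  df <- tibble::as_tibble(as.data.frame(set$channels))
  df <- dplyr::bind_cols(
    tibble(sample = seq_len(nrow(df)),
           trial = trial_index_of(set$trials, nrow(df)),
           support = set$support),
    df
  )
  readr::write_tsv(df, path)
  invisible(path)
}

# map each sample row to its trial id
trial_index_of <- function(trials, n) {
  idx <- integer(n)
  for (i in seq_len(nrow(trials))) idx[trials$start[i]:trials$end[i]] <- trials$trial[i]
  idx
}
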