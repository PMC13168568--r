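#' TRF lag axis
#'
#' Lag times for the kernel window, left-closed right-open: at 100 Hz the
#' window `[-50, 700)` ms in 10 ms steps yields exactly 75 lag points.
#'
#' @param lag_min_s,lag_max_s Window bounds in seconds (defaults -0.05, 0.7).
#' @param rate Grid rate in Hz (default 100).
#' @return Numeric vector of lag times in ms.
#' @export
#' @examples
#' length(lag_axis())  # 75
lag_axis <- function(lag_min_s = -0.05, lag_max_s = 0.7, rate = 100) {
  n <- as.integer(round((lag_max_s - lag_min_s) * rate))
  if (n < 1L) abort("Empty lag window.")
  seq(lag_min_s * 1000, by = 1000 / rate, length.out = n)
}

# Hamming basis window of the given width (seconds) at the grid rate
hamming_basis <- function(width_s = 0.05, rate = 100) {
  n <- max(1L, as.integer(round(width_s * rate)))
  if (n == 1L) return(1)
  k <- seq_len(n) - 1L
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

# channel smoothed with the centered basis window, per trial (no mixing
# across trial boundaries)
smooth_with_basis <- function(x, trials, h, align = c("center", "left")) {
  align <- match.arg(align)
  offset <- if (align == "center") -(length(h) %/% 2L) else 0L
  out <- numeric(length(x))
  for (ti in seq_len(nrow(trials))) {
    r <- trials$start[ti]:trials$end[ti]
    seg <- x[r]
    acc <- numeric(length(seg))
    for (j in seq_along(h)) {
      sh <- j - 1L + offset  # contribution of x[t - sh]
      src <- seq_along(seg) - sh
      ok <- src >= 1L & src <= length(seg)
      acc[ok] <- acc[ok] + h[j] * seg[src[ok]]
    }
    out[r] <- acc
  }
  out
}

#' Lagged Hamming-basis design
#'
#' Expands a (normalised, padded) predictor set into the TRF design: for
#' every channel and lag \eqn{\tau_k}, a regressor equal to the channel
#' convolved with a 50 ms Hamming window placed at \eqn{\tau_k}.
#' Regressors never mix samples across trial boundaries.  The default axis
#' is `[-50, 700)` ms at 10 ms steps (75 lags).
#'
#' @param set A `"predictor_set"`.
#' @param lag_min_s,lag_max_s Lag window in seconds.
#' @param basis_width_s Basis window width in seconds (default 0.05).
#' @param align `"center"` (default) or `"left"` alignment of the basis
#'   window on each lag.
#' @return A list of class `"lag_design"` with `X` (samples x regressors),
#'   `cols` (tibble: `channel`, `family`, `lag_ms`, `lag_samples`),
#'   `trials`, `support`, `rate`, `basis`.
#' @export
lag_expand <- function(set, lag_min_s = -0.05, lag_max_s = 0.7,
                       basis_width_s = 0.05, align = c("center", "left")) {
  align <- match.arg(align)
  stopifnot(inherits(set, "predictor_set"))
  lags_ms <- lag_axis(lag_min_s, lag_max_s, set$rate)
  lag_samp <- as.integer(round(lags_ms / 1000 * set$rate))
  h <- hamming_basis(basis_width_s, set$rate)
  n <- nrow(set$channels)
  C <- ncol(set$channels)
  p <- C * length(lag_samp)

  X <- matrix(0, n, p)
  cols <- tidyr::expand_grid(
    channel = colnames(set$channels),
    lag_ms = lags_ms
  )
  cols$family <- rep(set$families, each = length(lag_samp))
  cols$lag_samples <- rep(lag_samp, times = C)
  colnames(X) <- paste0(cols$channel, "@", cols$lag_ms, "ms")

  col <- 0L
  for (ci in seq_len(C)) {
    s <- smooth_with_basis(set$channels[, ci], set$trials, h, align)
    for (li in seq_along(lag_samp)) {
      col <- col + 1L
      L <- lag_samp[li]
      for (ti in seq_len(nrow(set$trials))) {
        r0 <- set$trials$start[ti]
        r1 <- set$trials$end[ti]
        len <- r1 - r0 + 1L
        t_idx <- seq_len(len)
        src <- t_idx - L
        ok <- src >= 1L & src <= len
        X[r0 - 1L + t_idx[ok], col] <- s[r0 - 1L + src[ok]]
      }
    }
  }
  structure(
    list(X = X, cols = cols[, c("channel", "family", "lag_ms", "lag_samples")],
         trials = set$trials, support = set$support, rate = set$rate,
         basis = h, align = align,
         cache = new.env(parent = emptyenv())),
    class = "lag_design"
  )
}

#' @export
print.lag_design <- function(x, ...) {
  cat(sprintf("<lag_design> %d samples x %d regressors (%d channels x %d lags) @ %g Hz\n",
              nrow(x$X), ncol(x$X), length(unique(x$cols$channel)),
              length(unique(x$cols$lag_ms)), x$rate))
  invisible(x)
}

#' Evaluate the forward model for a kernel
#'
#' Computes \eqn{y(t) = \sum_f \sum_k \beta_f(\tau_k) x_f(t - \tau_k)} in the
#' Hamming-basis parameterisation: the design matrix times the coefficient
#' vector (or matrix, one column per source).
#'
#' @param design A `"lag_design"`.
#' @param beta Numeric vector of length `ncol(design$X)`, or a matrix with
#'   one column per source.
#' @return Numeric vector or samples x sources matrix.
#' @export
forward_model <- function(design, beta) {
  stopifnot(inherits(design, "lag_design"))
  beta <- as.matrix(beta)
  if (nrow(beta) != ncol(design$X)) {
    abort("`beta` length does not match the design.")
  }
  design$X %*% beta
}
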