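#' ERB-spaced centre frequencies
#'
#' Frequencies equally spaced on the Glasberg–Moore ERB-number scale
#' \eqn{E(f) = 21.4 \log_{10}(1 + 0.00437 f)} between `fmin` and `fmax`,
#' endpoints included.
#'
#' @param fmin,fmax Frequency bounds in Hz, `0 < fmin < fmax`.
#' @param n Number of centres (>= 2).
#' @return Strictly increasing numeric vector of length `n`.
#' @export
#' @examples
#' erb_centers(20, 5000, 8)
erb_centers <- function(fmin, fmax, n) {
  assert_scalar_number(fmin, "fmin", positive = TRUE)
  assert_scalar_number(fmax, "fmax", positive = TRUE)
  if (fmin >= fmax) abort("`fmin` must be smaller than `fmax`.")
  if (!is.numeric(n) || n < 2) abort("`n` must be at least 2.")
  erb_num <- function(f) 21.4 * log10(1 + 0.00437 * f)
  erb_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437
  erb_inv(seq(erb_num(fmin), erb_num(fmax), length.out = n))
}

# ERB bandwidth (Hz) at centre frequency f
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

# FIR kernel of a 4th-order gammatone filter, peak-normalised so the
# magnitude response at the centre frequency is 1
gammatone_kernel <- function(cf, fs) {
  b <- 1.019 * erb_bandwidth(cf)
  # envelope t^3 exp(-2 pi b t) peaks at t = 3/(2 pi b); keep 12 further
  # time constants of decay
  dur <- 15 / (2 * pi * b)
  t <- seq(0, dur, by = 1 / fs)
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  h <- sum(g * exp(-2i * pi * cf * t))
  g / Mod(h)
}

# linear convolution via FFT, causal, trimmed to length(x)
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(x, numeric(nf - length(x)))) *
             fft(c(h, numeric(nf - length(h)))), inverse = TRUE)) / nf
  y[seq_along(x)]
}

#' Gammatone spectrogram on the predictor grid
#'
#' Filters audio through a bank of 4th-order gammatone filters with
#' ERB-spaced centre frequencies, extracts the per-band amplitude envelope
#' (half-wave rectification followed by a 4th-order Butterworth low-pass),
#' and resamples to the output rate.  No compression is applied.
#'
#' @param wave An `"audio_wave"` (list with `samples`, `rate`) or a numeric
#'   vector (then `sample_rate` is required).
#' @param sample_rate Sample rate in Hz when `wave` is a bare vector.
#' @param n_bands Number of bands (default 8).
#' @param fmin,fmax Band limits in Hz (defaults 20 and 5000).
#' @param out_rate Output frame rate in Hz (default 100).
#' @param env_lowpass Envelope low-pass cutoff in Hz (default 40).
#' @return A `"banded_envelope"`: list with `values` (frames x bands matrix,
#'   all values >= 0), `centers` (Hz), `rate` (Hz), `kind = "envelope"`.
#' @export
gammatone_spectrogram <- function(wave, sample_rate = NULL, n_bands = 8,
                                  fmin = 20, fmax = 5000, out_rate = 100,
                                  env_lowpass = 40) {
  if (inherits(wave, "audio_wave")) {
    sample_rate <- wave$rate
    x <- wave$samples
  } else {
    x <- as.numeric(wave)
  }
  if (is.null(sample_rate)) abort("`sample_rate` is required for bare sample vectors.")
  if (sample_rate < 2 * fmax) {
    abort(sprintf("Sample rate %g Hz is below the required minimum 2*fmax = %g Hz.",
                  sample_rate, 2 * fmax))
  }
  if (length(x) == 0L) abort("Audio has zero duration.")

  centers <- erb_centers(fmin, fmax, n_bands)
  n_frames <- as.integer(ceiling(length(x) / sample_rate * out_rate))
  lp <- signal::butter(4, min(env_lowpass / (sample_rate / 2), 0.99))
  g <- gcd_int(as.integer(out_rate), as.integer(sample_rate))
  p <- as.integer(out_rate) %/% g
  q <- as.integer(sample_rate) %/% g

  vals <- matrix(0, nrow = n_frames, ncol = n_bands)
  for (bi in seq_len(n_bands)) {
    band <- fft_conv(x, gammatone_kernel(centers[bi], sample_rate))
    env <- pmax(band, 0)
    env <- signal::filtfilt(lp, env)
    env <- signal::resample(env, p, q)
    env <- pmax(env, 0)
    if (length(env) >= n_frames) {
      vals[, bi] <- env[seq_len(n_frames)]
    } else {
      vals[seq_along(env), bi] <- env
    }
  }
  structure(list(values = vals, centers = centers, rate = out_rate,
                 kind = "envelope"),
            class = "banded_envelope")
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Acoustic onset (edge) spectrogram
#'
#' Half-wave rectified first derivative of the banded envelope: per band,
#' the first difference scaled by the frame rate with negative values
#' clipped to zero; the first frame is defined as zero.  This captures
#' sudden increases in the gammatone spectrogram ("acoustic edges") while
#' rejecting offsets.
#'
#' @param env A `"banded_envelope"` from [gammatone_spectrogram()].
#' @return A `"banded_envelope"` with `kind = "onset"`.
#' @export
onset_spectrogram <- function(env) {
  stopifnot(inherits(env, "banded_envelope"))
  d <- rbind(0, diff(env$values) * env$rate)
  d[d < 0] <- 0
  structure(list(values = d, centers = env$centers, rate = env$rate,
                 kind = "onset"),
            class = "banded_envelope")
}

#' @export
print.banded_envelope <- function(x, ...) {
  cat(sprintf("<banded_envelope:%s> %d frames x %d bands @ %g Hz (%.4g-%.4g Hz)\n",
              x$kind, nrow(x$values), ncol(x$values), x$rate,
              min(x$centers), max(x$centers)))
  invisible(x)
}

#' @describeIn gammatone_spectrogram Long-format view: one row per
#'   (frame, band) with `time_s`, `band`, `center_hz`, `value`.
#' @param x A `"banded_envelope"`.
#' @param ... Unused.
#' @export
tidy.banded_envelope <- function(x, ...) {
  n <- nrow(x$values)
  tidyr::expand_grid(frame = seq_len(n), band = seq_along(x$centers)) |>
    dplyr::mutate(
      time_s = (.data$frame - 1) / x$rate,
      center_hz = x$centers[.data$band],
      value = x$values[cbind(.data$frame, .data$band)]
    ) |>
    dplyr::select("time_s", "band", "center_hz", "value")
}

#' @describeIn gammatone_spectrogram Heat-map of the banded envelope.
#' @param object A `"banded_envelope"`.
#' @export
autoplot.banded_envelope <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_s, factor(round(.data$center_hz)),
                                 fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = "Time (s)", y = "Band centre (Hz)",
                  title = if (object$kind == "onset") "Acoustic onset spectrogram"
                          else "Gammatone spectrogram")
}

#' Export a banded envelope as TSV
#'
#' One column per band (named by centre frequency) plus `time_s`.
#' @param env A `"banded_envelope"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_banded_tsv <- function(env, path) {
  df <- as.data.frame(env$values)
  names(df) <- sprintf("band_%.6ghz", env$centers)
  df <- cbind(time_s = (seq_len(nrow(df)) - 1) / env$rate, df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
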