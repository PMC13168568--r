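# Minimal RIFF/WAVE reader and writer: PCM 16/24-bit and IEEE float-32,
# which covers the synthesized stimuli and typical speech recordings.

#' Read a WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float-32 RIFF/WAVE files.
#' Stereo files are averaged to mono with a warning (the feature pipeline
#' is mono).
#'
#' @param path Path to the WAV file.
#' @param to_mono Average channels to mono (default `TRUE`).
#' @return A list of class `"audio_wave"` with elements `samples` (numeric
#'   vector or channel matrix, full scale in \eqn{[-1, 1]}) and `rate` (Hz).
#' @export
read_wav <- function(path, to_mono = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF/WAVE file.")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a RIFF/WAVE file.")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(body[3:4], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(body[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(body[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("Malformed WAV: missing fmt or data chunk.")

  fmt_code <- fmt$audio_format
  if (fmt_code == 65534L) fmt_code <- if (fmt$bits == 32L) 3L else 1L
  x <- switch(
    as.character(fmt_code),
    "1" = {
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
                endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) %/% 3L
        b <- matrix(as.integer(data_raw), nrow = 3L)[, seq_len(n), drop = FALSE]
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        abort(sprintf("Unsupported PCM bit depth: %d.", fmt$bits))
      }
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4L, size = 4,
                  endian = "little"),
    abort(sprintf("Unsupported WAV format code: %d.", fmt$audio_format))
  )

  if (fmt$n_channels > 1L) {
    x <- matrix(x, nrow = fmt$n_channels)
    if (to_mono) {
      warn(sprintf("Averaging %d channels to mono.", fmt$n_channels))
      x <- colMeans(x)
    } else {
      x <- t(x)
    }
  }
  structure(list(samples = x, rate = fmt$sample_rate), class = "audio_wave")
}

#' Write a mono WAV file (PCM 16-bit)
#'
#' @param samples Numeric vector in \eqn{[-1, 1]} (values are clipped).
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  if (inherits(samples, "audio_wave")) {
    rate <- samples$rate
    samples <- samples$samples
  }
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
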