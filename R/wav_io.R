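#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings produced by field
#' recorders and by [write_wav()]: 16- and 24-bit integer PCM and 32-bit
#' IEEE float, any number of channels. Samples are returned as doubles
#' scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (matrix, channels x frames) and `rate` (Hz).
#' @seealso [load_audio()] for the mono, resampled view used by the
#'   feature pipeline.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(sprintf("WAV file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(sprintf("not a RIFF file: %s", path))
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(sprintf("not a WAVE file: %s", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size, origin = "current")
    }
    if (size %% 2 == 1) seek(con, 1, origin = "current") # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("corrupt WAV (missing fmt/data chunk): %s", path))
  }
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real format in the
  # extension; treat it as PCM, which is what recorders emit.
  if (!fmt$audio_format %in% c(1L, 3L, -2L, 65534L)) {
    abort(sprintf("unsupported WAV encoding %d in %s", fmt$audio_format, path))
  }

  n_bytes <- fmt$bits %/% 8
  n_samp <- length(data_raw) %/% (n_bytes * fmt$channels)
  if (n_samp == 0) abort(sprintf("zero-length audio: %s", path))

  if (fmt$audio_format == 3L || fmt$bits == 32L && fmt$audio_format != 1L) {
    x <- readBin(data_raw, "double", n = n_samp * fmt$channels, size = 4,
                 endian = "little")
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n = n_samp * fmt$channels, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    i0 <- seq(1L, length(b), by = 3L)
    v <- b[i0] + 256 * b[i0 + 1L] + 65536 * b[i0 + 2L]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    abort(sprintf("unsupported bit depth %d in %s", fmt$bits, path))
  }
  list(samples = matrix(x, nrow = fmt$channels), rate = fmt$sample_rate)
}

#' Write a PCM WAV file
#'
#' @param samples Numeric vector (mono) or channels x frames matrix, in
#'   \[-1, 1\]. Values outside that range are clipped.
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @param bits Bit depth: 16 (default) or 24 integer PCM, or 32 for float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot_scalar_num(rate, "rate", lower = 1)
  if (!bits %in% c(16, 24, 32)) abort("`bits` must be 16, 24 or 32")
  n_ch <- nrow(samples)
  x <- as.numeric(samples) # interleaved: channels vary fastest (column-major)
  x <- pmin(pmax(x, -1), 1)

  if (bits == 32) {
    body <- writeBin(x, raw(), size = 4, endian = "little")
    fmt_code <- 3L
  } else if (bits == 16) {
    q <- as.integer(round(x * 32767))
    body <- writeBin(q, raw(), size = 2, endian = "little")
    fmt_code <- 1L
  } else {
    q <- round(x * 8388607)
    q <- ifelse(q < 0, q + 16777216, q)
    b <- integer(3 * length(q))
    b[seq(1, length(b), 3)] <- q %% 256
    b[seq(2, length(b), 3)] <- (q %/% 256) %% 256
    b[seq(3, length(b), 3)] <- (q %/% 65536) %% 256
    body <- as.raw(b)
    fmt_code <- 1L
  }

  byte_rate <- as.integer(rate * n_ch * bits / 8)
  block_align <- as.integer(n_ch * bits / 8)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(body)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(body)), con, size = 4, endian = "little")
  writeBin(body, con)
  invisible(path)
}

#' Load audio as a mono waveform at a target sample rate
#'
#' Multi-channel audio is averaged to mono, then polyphase-resampled to
#' `target_rate` (the pipeline standard is 22.05 kHz, the rate all
#' recordings are normalized to before feature extraction).
#'
#' @param path Path to a PCM WAV file.
#' @param target_rate Desired sample rate in Hz (default 22050).
#' @return A `waveform` object: list with `samples` (numeric vector in
#'   \[-1, 1\]) and `rate`.
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".wav")
#' write_wav(sin(2 * pi * 440 * seq(0, 1, by = 1 / 44100)), 44100, f)
#' w <- load_audio(f, 22050)
#' w$rate
#' }
#' @export
load_audio <- function(path, target_rate = 22050) {
  stopifnot_scalar_num(target_rate, "target_rate", lower = 0, strict_lower = TRUE)
  raw <- read_wav(path)
  x <- if (nrow(raw$samples) > 1) colMeans(raw$samples) else as.numeric(raw$samples)
  if (length(x) == 0) abort(sprintf("zero-length audio: %s", path))
  if (raw$rate != target_rate) {
    g <- gcd_int(target_rate, raw$rate)
    x <- signal::resample(x, target_rate / g, raw$rate / g)
    # keep the canonical length round(n * target/orig)
    n_out <- round(length(raw$samples[1, ]) * target_rate / raw$rate)
    if (length(x) > n_out) x <- x[seq_len(n_out)]
  }
  x <- pmin(pmax(as.numeric(x), -1), 1)
  structure(list(samples = x, rate = target_rate), class = "waveform")
}

gcd_int <- function(a, b) {
  a <- abs(round(a)); b <- abs(round(b))
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}
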