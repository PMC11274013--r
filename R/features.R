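#' Mel-spectrogram configuration
#'
#' Defaults follow the standard bioacoustic few-shot recipe: 22.05 kHz
#' audio, 1024-point FFT, 128 Mel bands, a 256-sample STFT hop
#' (frame hop ~11.6 ms), and 0.04 s / 0.02 s patch length / patch hop for
#' grouping frames into fixed-size encoder inputs. `eps` is the floor
#' applied to Mel energies so downstream logs/compressions never see 0.
#'
#' @param sample_rate Sample rate in Hz.
#' @param n_fft FFT size in samples.
#' @param n_mel Number of Mel bands.
#' @param hop_mel STFT hop in samples.
#' @param seg_len_s Patch length in seconds (frames grouped per encoder input).
#' @param seg_hop_s Patch hop in seconds.
#' @param eps Lower bound on Mel energies.
#' @param center Logical; centered STFT frames with reflect padding
#'   (default), giving `floor(n / hop) + 1` frames.
#' @return A `mel_config` list.
#' @export
mel_config <- function(sample_rate = 22050, n_fft = 1024, n_mel = 128,
                       hop_mel = 256, seg_len_s = 0.04, seg_hop_s = 0.02,
                       eps = 2.2204e-16, center = TRUE) {
  stopifnot_scalar_num(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  stopifnot_scalar_num(n_fft, "n_fft", 1)
  stopifnot_scalar_num(n_mel, "n_mel", 1)
  stopifnot_scalar_num(hop_mel, "hop_mel", 1)
  stopifnot_scalar_num(eps, "eps", 0, strict_lower = TRUE)
  if (n_fft < hop_mel) abort("`n_fft` must be >= `hop_mel`")
  structure(list(sample_rate = sample_rate, n_fft = as.integer(n_fft),
                 n_mel = as.integer(n_mel), hop_mel = as.integer(hop_mel),
                 seg_len_s = seg_len_s, seg_hop_s = seg_hop_s, eps = eps,
                 center = isTRUE(center)),
            class = "mel_config")
}

#' PCEN configuration
#'
#' Per-channel energy normalization: an automatic gain control (first-order
#' IIR smoother `M` per Mel band, coefficient `smoothing_coef`) followed by
#' root compression: `(E / (eps + M)^gain_alpha + bias_delta)^root_r -
#' bias_delta^root_r`. Defaults are the settings commonly used for
#' bioacoustic recordings.
#'
#' @param smoothing_coef IIR smoothing coefficient in (0, 1].
#' @param gain_alpha AGC gain exponent.
#' @param bias_delta Bias added before root compression.
#' @param root_r Compression root, in (0, 1].
#' @param eps Stabilizer in the AGC denominator.
#' @return A `pcen_config` list.
#' @export
pcen_config <- function(smoothing_coef = 0.025, gain_alpha = 0.98,
                        bias_delta = 2.0, root_r = 0.5, eps = 1e-6) {
  stopifnot_scalar_num(smoothing_coef, "smoothing_coef", 0, 1, strict_lower = TRUE)
  stopifnot_scalar_num(gain_alpha, "gain_alpha", 0, strict_lower = TRUE)
  stopifnot_scalar_num(bias_delta, "bias_delta", 0)
  stopifnot_scalar_num(root_r, "root_r", 0, 1, strict_lower = TRUE)
  stopifnot_scalar_num(eps, "eps", 0, strict_lower = TRUE)
  structure(list(smoothing_coef = smoothing_coef, gain_alpha = gain_alpha,
                 bias_delta = bias_delta, root_r = root_r, eps = eps),
            class = "pcen_config")
}

new_spectrogram <- function(values, frame_hop_s, start_time_s = 0,
                            sample_rate = NA_real_) {
  structure(list(values = values, frame_hop_s = frame_hop_s,
                 start_time_s = start_time_s, sample_rate = sample_rate),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bands, hop %.4f s, start %.3f s\n",
              nrow(x$values), ncol(x$values), x$frame_hop_s, x$start_time_s))
  invisible(x)
}

# Triangular Mel filterbank (HTK mel scale, unnormalized triangles),
# rows = bands, cols = FFT bins 0..n_fft/2.
mel_filterbank <- function(sample_rate, n_fft, n_mel,
                           fmin = 0, fmax = sample_rate / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mel + 2))
  bins <- (0:(n_fft %/% 2)) * sample_rate / n_fft
  fb <- matrix(0, n_mel, length(bins))
  for (m in seq_len(n_mel)) {
    lo <- pts[m]; cen <- pts[m + 1]; hi <- pts[m + 2]
    up <- (bins - lo) / (cen - lo)
    down <- (hi - bins) / (hi - cen)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "center_hz") <- pts[2:(n_mel + 1)]
  fb
}

#' Compute a Mel spectrogram
#'
#' Hann-windowed STFT power spectrum mapped through a triangular Mel
#' filterbank. With `center = TRUE` frames are centered with reflect
#' padding, giving `floor(n / hop) + 1` frames; otherwise
#' `floor((n - n_fft) / hop) + 1`. Output energies are floored at
#' `cfg$eps`.
#'
#' @param w A `waveform` (from [load_audio()]) or numeric vector at
#'   `cfg$sample_rate`.
#' @param cfg A [mel_config()].
#' @return A `spectrogram`: `values` is frames x bands, non-negative.
#' @export
mel_spectrogram <- function(w, cfg = mel_config()) {
  x <- if (inherits(w, "waveform")) w$samples else as.numeric(w)
  if (inherits(w, "waveform") && w$rate != cfg$sample_rate) {
    abort(sprintf("waveform rate %g != config sample_rate %g",
                  w$rate, cfg$sample_rate))
  }
  n <- length(x)
  n_fft <- cfg$n_fft; hop <- cfg$hop_mel
  if (n < n_fft) abort(sprintf("waveform (%d samples) shorter than one FFT window (%d)", n, n_fft))

  if (cfg$center) {
    half <- n_fft %/% 2
    # reflect padding (no repeated edge sample)
    xp <- c(rev(x[2:(half + 1)]), x, rev(x[(n - half):(n - 1)]))
    starts <- seq(1L, by = hop, length.out = n %/% hop + 1L)
  } else {
    xp <- x
    starts <- seq(1L, by = hop, length.out = (n - n_fft) %/% hop + 1L)
  }
  idx <- outer(0:(n_fft - 1L), starts, "+")
  frames <- matrix(xp[idx], nrow = n_fft)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n_fft - 1)) / n_fft) # periodic Hann
  frames <- frames * win
  spec <- stats::mvfft(frames)[1:(n_fft %/% 2 + 1), , drop = FALSE]
  pow <- Re(spec)^2 + Im(spec)^2

  fb <- mel_filterbank(cfg$sample_rate, n_fft, cfg$n_mel)
  mel <- t(fb %*% pow) # frames x bands
  mel[mel < cfg$eps] <- cfg$eps
  if (any(!is.finite(mel))) abort("non-finite values in Mel spectrogram")
  s <- new_spectrogram(mel, frame_hop_s = hop / cfg$sample_rate,
                       start_time_s = 0, sample_rate = cfg$sample_rate)
  attr(s, "band_center_hz") <- attr(fb, "center_hz")
  s
}

#' Apply per-channel energy normalization
#'
#' @param s A `spectrogram` with non-negative values, or a frames x bands
#'   matrix.
#' @param cfg A [pcen_config()].
#' @return Object of the same type, PCEN-transformed, shape unchanged.
#' @export
pcen <- function(s, cfg = pcen_config()) {
  is_spec <- inherits(s, "spectrogram")
  E <- if (is_spec) s$values else s
  if (any(!is.finite(E))) abort("non-finite values in PCEN input")
  if (any(E < 0)) abort("PCEN input must be non-negative")
  b <- cfg$smoothing_coef
  M <- E
  if (nrow(E) > 1) {
    for (t in 2:nrow(E)) M[t, ] <- (1 - b) * M[t - 1, ] + b * E[t, ]
  }
  out <- (E / (cfg$eps + M)^cfg$gain_alpha + cfg$bias_delta)^cfg$root_r -
    cfg$bias_delta^cfg$root_r
  if (is_spec) {
    s$values <- out
    s
  } else {
    out
  }
}

#' Start time of a spectrogram frame
#'
#' Frame `i` (0-based) covers the half-open interval
#' `[start_time_s + i * frame_hop_s, start_time_s + (i + 1) * frame_hop_s)`.
#'
#' @param s A `spectrogram`.
#' @param i Frame index, 0-based; `0 <= i < n_frames`.
#' @return Start time in seconds.
#' @export
frame_time <- function(s, i) {
  n <- nrow(s$values)
  if (any(i < 0 | i >= n)) abort(sprintf("frame index out of range [0, %d)", n))
  s$start_time_s + i * s$frame_hop_s
}

#' Cut a spectrogram into fixed-length patches
#'
#' Groups consecutive frames into patches of `ceiling(seg_len_s /
#' frame_hop_s)` frames, advancing by `max(1, round(seg_hop_s /
#' frame_hop_s))` frames. These patches are the unit fed to the encoder.
#'
#' @param s A `spectrogram`.
#' @param cfg The [mel_config()] providing `seg_len_s` / `seg_hop_s`.
#' @return A list with `patches` (3-D array, patch x frame x band) and
#'   `info`, a tibble with one row per patch: `start_s`, `end_s`,
#'   `first_frame`, `last_frame` (1-based frame indices).
#' @export
make_patches <- function(s, cfg = mel_config()) {
  plen <- patch_len_frames(cfg)
  phop <- patch_hop_frames(cfg)
  n <- nrow(s$values)
  if (n < plen) abort(sprintf("spectrogram has %d frames; need >= %d per patch", n, plen))
  firsts <- seq(1L, n - plen + 1L, by = phop)
  arr <- array(0, dim = c(length(firsts), plen, ncol(s$values)))
  for (j in seq_along(firsts)) {
    arr[j, , ] <- s$values[firsts[j]:(firsts[j] + plen - 1L), ]
  }
  info <- tibble::tibble(
    first_frame = firsts,
    last_frame = firsts + plen - 1L,
    start_s = s$start_time_s + (firsts - 1) * s$frame_hop_s,
    end_s = s$start_time_s + (firsts - 1 + plen) * s$frame_hop_s
  )
  list(patches = arr, info = info)
}

patch_len_frames <- function(cfg) as.integer(ceiling(cfg$seg_len_s / (cfg$hop_mel / cfg$sample_rate)))
patch_hop_frames <- function(cfg) max(1L, as.integer(round(cfg$seg_hop_s / (cfg$hop_mel / cfg$sample_rate))))

# Extract one patch per window for the frames inside [onset_s, offset_s];
# intervals shorter than one patch are tiled (frames repeated) to patch
# length, the conventional treatment of very short calls.
patches_for_interval <- function(s, cfg, onset_s, offset_s) {
  hop <- s$frame_hop_s
  plen <- patch_len_frames(cfg)
  phop <- patch_hop_frames(cfg)
  f0 <- max(1L, 1L + as.integer(floor((onset_s - s$start_time_s) / hop)))
  f1 <- min(nrow(s$values), as.integer(ceiling((offset_s - s$start_time_s) / hop)))
  if (f1 < f0) return(list())
  seg <- s$values[f0:f1, , drop = FALSE]
  if (nrow(seg) < plen) {
    return(list(tile_frames(seg, plen)))
  }
  firsts <- seq(1L, nrow(seg) - plen + 1L, by = phop)
  lapply(firsts, function(f) seg[f:(f + plen - 1L), , drop = FALSE])
}

# Repeat frames cyclically until at least `n` rows (already-long inputs
# pass through unchanged), then crop to exactly `n` when tiling occurred.
tile_frames <- function(m, n) {
  if (nrow(m) >= n) return(m)
  reps <- ceiling(n / nrow(m))
  out <- m[rep(seq_len(nrow(m)), reps), , drop = FALSE]
  out[seq_len(n), , drop = FALSE]
}
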