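#' SpecAugment configuration
#'
#' Spectrogram-domain augmentation used during encoder pre-training:
#' time masking, frequency masking, and time warping. Widths are maxima of
#' discrete uniform draws; zero widths make the corresponding operator an
#' identity.
#'
#' @param t_max Maximum time-mask width in frames.
#' @param f_max Maximum frequency-mask width in Mel bands.
#' @param n_time_masks,n_freq_masks Number of masks applied per call.
#' @param warp_w Maximum anchor displacement for time warping, in frames.
#' @param fill_value Value written into masked cells (0 after PCEN; set to
#'   the per-spectrogram mean via `fill_value = "mean"`).
#' @param warp,mask_time,mask_freq Logical enable flags per operator.
#' @return An `augment_config` list.
#' @export
augment_config <- function(t_max = 2, f_max = 13, n_time_masks = 2,
                           n_freq_masks = 2, warp_w = 5, fill_value = 0,
                           warp = TRUE, mask_time = TRUE, mask_freq = TRUE) {
  stopifnot_scalar_num(t_max, "t_max", 0)
  stopifnot_scalar_num(f_max, "f_max", 0)
  stopifnot_scalar_num(warp_w, "warp_w", 0)
  stopifnot_scalar_num(n_time_masks, "n_time_masks", 0)
  stopifnot_scalar_num(n_freq_masks, "n_freq_masks", 0)
  structure(list(t_max = as.integer(t_max), f_max = as.integer(f_max),
                 n_time_masks = as.integer(n_time_masks),
                 n_freq_masks = as.integer(n_freq_masks),
                 warp_w = as.integer(warp_w), fill_value = fill_value,
                 warp = isTRUE(warp), mask_time = isTRUE(mask_time),
                 mask_freq = isTRUE(mask_freq)),
            class = "augment_config")
}

aug_values <- function(s) if (inherits(s, "spectrogram")) s$values else s
aug_rewrap <- function(s, v) {
  if (inherits(s, "spectrogram")) { s$values <- v; s } else v
}
aug_fill <- function(v, cfg) {
  if (identical(cfg$fill_value, "mean")) mean(v) else cfg$fill_value
}

#' Mask a random time segment
#'
#' Draws a width `t ~ U{0, ..., t_max}` and a start `t0 ~ U{0, ...,
#' n_frames - t}`, then sets frames `[t0, t0 + t)` to the fill value.
#'
#' @param s A `spectrogram` or frames x bands matrix.
#' @param cfg An [augment_config()].
#' @param seed Optional integer seed for the draw (the caller's RNG state
#'   is untouched when given).
#' @return Same type as `s`; the drawn width/start are attached as
#'   attributes `mask_width` and `mask_start` (0-based).
#' @export
time_mask <- function(s, cfg = augment_config(), seed = NULL) {
  v <- aug_values(s)
  n <- nrow(v)
  if (cfg$t_max > n) abort(sprintf("t_max (%d) exceeds n_frames (%d)", cfg$t_max, n))
  draws <- with_seed(seed, {
    t <- sample.int(cfg$t_max + 1L, 1L) - 1L
    t0 <- sample.int(n - t + 1L, 1L) - 1L
    c(t, t0)
  })
  t <- draws[1]; t0 <- draws[2]
  if (t > 0) v[(t0 + 1L):(t0 + t), ] <- aug_fill(aug_values(s), cfg)
  out <- aug_rewrap(s, v)
  attr(out, "mask_width") <- t
  attr(out, "mask_start") <- t0
  out
}

#' Mask a random frequency band
#'
#' As [time_mask()], along the Mel axis with width `f ~ U{0, ..., f_max}`.
#'
#' @inheritParams time_mask
#' @return Same type as `s`, with attributes `mask_width`, `mask_start`.
#' @export
freq_mask <- function(s, cfg = augment_config(), seed = NULL) {
  v <- aug_values(s)
  n <- ncol(v)
  if (cfg$f_max > n) abort(sprintf("f_max (%d) exceeds n_mel (%d)", cfg$f_max, n))
  draws <- with_seed(seed, {
    f <- sample.int(cfg$f_max + 1L, 1L) - 1L
    f0 <- sample.int(n - f + 1L, 1L) - 1L
    c(f, f0)
  })
  f <- draws[1]; f0 <- draws[2]
  if (f > 0) v[, (f0 + 1L):(f0 + f)] <- aug_fill(aug_values(s), cfg)
  out <- aug_rewrap(s, v)
  attr(out, "mask_width") <- f
  attr(out, "mask_start") <- f0
  out
}

#' Warp the time axis around a random anchor
#'
#' Picks an anchor frame `a ~ U{warp_w, ..., n_frames - warp_w}` (0-based)
#' and displacement `w ~ U{-warp_w, ..., warp_w}`, then piecewise-linearly
#' resamples the time axis so input frame `a` lands at output position
#' `a + w`, with both endpoints fixed. Shape is unchanged.
#'
#' @inheritParams time_mask
#' @return Same type as `s`, with attributes `warp_anchor`, `warp_shift`.
#' @export
time_warp <- function(s, cfg = augment_config(), seed = NULL) {
  v <- aug_values(s)
  n <- nrow(v)
  if (cfg$warp_w >= n / 2) abort(sprintf("warp_w (%d) must be < n_frames/2 (%g)", cfg$warp_w, n / 2))
  draws <- with_seed(seed, {
    a <- sample(cfg$warp_w:(n - 1L - cfg$warp_w), 1L)
    w <- sample((-cfg$warp_w):cfg$warp_w, 1L)
    c(a, w)
  })
  a <- draws[1]; w <- draws[2]
  out_v <- v
  if (cfg$warp_w > 0 && w != 0) {
    # output position j (1-based) reads input position src(j); the map is
    # linear on [1, a+w+1] -> [1, a+1] and [a+w+1, n] -> [a+1, n]
    j <- seq_len(n)
    ap <- a + w + 1 # 1-based output position of the anchor
    ai <- a + 1     # 1-based input position of the anchor
    src <- ifelse(j <= ap,
                  1 + (j - 1) * (ai - 1) / max(ap - 1, 1),
                  ai + (j - ap) * (n - ai) / max(n - ap, 1))
    lo <- pmin(floor(src), n); hi <- pmin(lo + 1, n)
    fr <- src - lo
    out_v <- (1 - fr) * v[lo, , drop = FALSE] + fr * v[hi, , drop = FALSE]
  }
  out <- aug_rewrap(s, out_v)
  attr(out, "warp_anchor") <- a
  attr(out, "warp_shift") <- w
  out
}

#' Compose the SpecAugment operators
#'
#' Applies, in this fixed order: time warp, then `n_time_masks` time
#' masks, then `n_freq_masks` frequency masks (each subject to its enable
#' flag). All randomness comes from the current RNG state, or from `seed`.
#'
#' @inheritParams time_mask
#' @return Same type and shape as `s`.
#' @export
augment <- function(s, cfg = augment_config(), seed = NULL) {
  with_seed(seed, {
    out <- s
    if (cfg$warp && cfg$warp_w > 0) out <- time_warp(out, cfg)
    if (cfg$mask_time && cfg$n_time_masks > 0) {
      for (i in seq_len(cfg$n_time_masks)) out <- time_mask(out, cfg)
    }
    if (cfg$mask_freq && cfg$n_freq_masks > 0) {
      for (i in seq_len(cfg$n_freq_masks)) out <- freq_mask(out, cfg)
    }
    attributes(out)[c("mask_width", "mask_start", "warp_anchor", "warp_shift")] <- NULL
    out
  })
}
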