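#' Detection / segmentation configuration
#'
#' Controls how per-frame positive posteriors become discrete events and
#' which predictions the shot-length post-filter removes.
#'
#' @param threshold Posterior cut in (0, 1).
#' @param median_win Median-filter window in frames (odd; 1 disables).
#' @param merge_gap_s Merge events separated by gaps of at most this many
#'   seconds (0 = no merging).
#' @param min_dur_frac Remove predicted events shorter than this fraction
#'   of the shortest provided shot (the reference rule uses 0.6).
#' @param k_shot Annotated positive events per file that form the support
#'   (the "first K shots" convention; default 5).
#' @return A `detection_config` list.
#' @export
detection_config <- function(threshold = 0.5, median_win = 5,
                             merge_gap_s = 0, min_dur_frac = 0.6, k_shot = 5) {
  stopifnot_scalar_num(threshold, "threshold", 0, 1, strict_lower = TRUE)
  if (threshold >= 1) abort("`threshold` must be < 1")
  stopifnot_scalar_num(median_win, "median_win", 1)
  stopifnot_scalar_num(merge_gap_s, "merge_gap_s", 0)
  stopifnot_scalar_num(min_dur_frac, "min_dur_frac", 0, 1)
  stopifnot_scalar_num(k_shot, "k_shot", 1)
  structure(list(threshold = threshold, median_win = as.integer(median_win),
                 merge_gap_s = merge_gap_s, min_dur_frac = min_dur_frac,
                 k_shot = as.integer(k_shot)),
            class = "detection_config")
}

#' Segment per-frame posteriors into events
#'
#' Median-filters the posterior track, thresholds it (`>= threshold`),
#' and turns maximal runs of positive frames into events; runs separated
#' by at most `merge_gap_s` are merged. Frame `i` (0-based) covers
#' `[start_s + i * hop_s, start_s + (i + 1) * hop_s)`, so an event spans
#' from the first frame's start to `(last frame index + 1) * hop_s`. The
#' event score is the mean filtered posterior over its frames.
#'
#' @param probs Per-frame positive-class posterior in \[0, 1\].
#' @param hop_s Frame hop in seconds.
#' @param cfg A [detection_config()].
#' @param start_s Time of frame 0 (default 0).
#' @param label Label for the returned events.
#' @return Event tibble with `score`; empty input gives an empty table.
#' @export
frames_to_events <- function(probs, hop_s, cfg = detection_config(),
                             start_s = 0, label = "event") {
  if (!length(probs)) {
    return(event_table(numeric(0), numeric(0), label = character(0),
                       score = numeric(0)))
  }
  if (any(probs < 0 | probs > 1)) abort("`probs` must lie in [0, 1]")
  p <- probs
  if (cfg$median_win > 1 && length(p) >= cfg$median_win) {
    k <- cfg$median_win
    if (k %% 2 == 0) k <- k + 1L
    p <- stats::runmed(p, k, endrule = "median")
  }
  mask <- p >= cfg$threshold
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on_idx <- which(runs$values)
  if (!length(on_idx)) {
    out <- event_table(numeric(0), numeric(0), label = character(0),
                       score = numeric(0))
    attr(out, "post_mask") <- mask
    return(out)
  }
  seg <- data.frame(first = starts[on_idx], last = ends[on_idx])
  # merge runs separated by short gaps
  if (cfg$merge_gap_s > 0 && nrow(seg) > 1) {
    merged <- seg[1, ]
    for (i in 2:nrow(seg)) {
      gap_s <- (seg$first[i] - merged$last[nrow(merged)] - 1) * hop_s
      if (gap_s <= cfg$merge_gap_s) {
        merged$last[nrow(merged)] <- seg$last[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  onset <- start_s + (seg$first - 1) * hop_s
  offset <- start_s + seg$last * hop_s
  score <- vapply(seq_len(nrow(seg)),
                  function(i) mean(p[seg$first[i]:seg$last[i]]), numeric(1))
  out <- event_table(onset, offset, label = label, score = score)
  attr(out, "post_mask") <- mask
  out
}

#' Remove predictions shorter than a fraction of the shortest shot
#'
#' The post-processing rule applied after detection: events with duration
#' below `min_dur_frac` times the shortest support shot of the file are
#' dropped (boundary kept: `>=` passes). Order is preserved.
#'
#' @param events Predicted event tibble.
#' @param shots Event tibble of the support shots (non-empty).
#' @param min_dur_frac Fraction of the shortest shot duration.
#' @return The filtered event tibble (a subset of `events`).
#' @export
filter_short_events <- function(events, shots, min_dur_frac = 0.6) {
  if (is.null(shots) || nrow(shots) == 0) abort("`shots` must be non-empty")
  stopifnot_scalar_num(min_dur_frac, "min_dur_frac", 0, 1)
  cut <- min_dur_frac * min(shots$offset_s - shots$onset_s)
  # small slack so durations exactly at the cut survive float arithmetic
  dplyr::filter(events, .data$offset_s - .data$onset_s >= cut - 1e-9)
}
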