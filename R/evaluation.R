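#' Intersection-over-union of two time intervals
#'
#' Half-open intervals; disjoint pairs give 0. Vectorized over all four
#' arguments.
#'
#' @param a_onset,a_offset,b_onset,b_offset Interval boundaries in
#'   seconds.
#' @return IoU in \[0, 1\].
#' @export
interval_iou <- function(a_onset, a_offset, b_onset, b_offset) {
  inter <- pmax(0, pmin(a_offset, b_offset) - pmax(a_onset, b_onset))
  union <- (a_offset - a_onset) + (b_offset - b_onset) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Match predicted events against ground truth
#'
#' Builds the bipartite graph between POS ground-truth events and
#' predictions with IoU at least `iou_min` (the reference setting is
#' 30%), and takes a maximum-cardinality matching, breaking ties by
#' maximal total IoU. Matched pairs are true positives; unmatched POS
#' events are false negatives. Unmatched predictions that overlap a UNK
#' ground-truth event at IoU >= `iou_min` are discarded (ambiguous
#' regions count neither way); the rest are false positives.
#'
#' @param gt Ground-truth event tibble with a `status` column (`POS`
#'   rows are scored, `UNK` rows shield predictions, others ignored).
#' @param pred Predicted event tibble.
#' @param iou_min Minimum IoU for a candidate match.
#' @return A `match_result`: list with `tp`, `fp`, `fn` and `pairs`
#'   (tibble `gt`, `pred`, `iou` of matched index pairs into the POS
#'   subset / predictions).
#' @export
match_events <- function(gt, pred, iou_min = 0.3) {
  stopifnot_scalar_num(iou_min, "iou_min", 0)
  pos <- if ("status" %in% names(gt)) gt[gt$status == "POS", , drop = FALSE] else gt
  unk <- if ("status" %in% names(gt)) gt[gt$status == "UNK", , drop = FALSE] else gt[0, ]
  n_pos <- nrow(pos); n_pred <- nrow(pred)

  pairs <- tibble::tibble(gt = integer(0), pred = integer(0), iou = numeric(0))
  if (n_pos > 0 && n_pred > 0) {
    iou <- outer(seq_len(n_pos), seq_len(n_pred), function(i, j) {
      interval_iou(pos$onset_s[i], pos$offset_s[i],
                   pred$onset_s[j], pred$offset_s[j])
    })
    edges <- which(iou >= iou_min, arr.ind = TRUE)
    if (nrow(edges) > 0) {
      m <- max_matching(edges, iou[edges], n_pos, n_pred)
      pairs <- tibble::tibble(gt = as.integer(m[, 1]),
                              pred = as.integer(m[, 2]),
                              iou = iou[m])
    }
  }
  tp <- nrow(pairs)
  fn <- n_pos - tp
  un_pred <- setdiff(seq_len(n_pred), pairs$pred)
  if (length(un_pred) && nrow(unk) > 0) {
    shielded <- vapply(un_pred, function(j) {
      any(interval_iou(unk$onset_s, unk$offset_s,
                       pred$onset_s[j], pred$offset_s[j]) >= iou_min)
    }, logical(1))
    un_pred <- un_pred[!shielded]
  }
  structure(list(tp = tp, fp = length(un_pred), fn = fn, pairs = pairs),
            class = "match_result")
}

# Maximum-cardinality bipartite matching with total IoU as tie-break,
# solved as maximum-weight matching with weights C + iou, C large enough
# that cardinality always dominates.
max_matching <- function(edges, weights, n_left, n_right) {
  C <- min(n_left, n_right) + 1
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n_left), rep(TRUE, n_right)),
    edges = as.vector(t(cbind(edges[, 1], n_left + edges[, 2])))
  )
  mm <- igraph::max_bipartite_match(g, weights = C + weights)
  partner <- mm$matching[seq_len(n_left)]
  matched <- which(!is.na(partner))
  cbind(gt = matched, pred = as.integer(partner[matched]) - n_left)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F-score from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F = 2PR / (P + R)`, with
#' any 0/0 defined as 0.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return Tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`.
#' @export
precision_recall_fscore <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative")
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f_score = f_score_from_pr(p, r))
}

#' F-score as the harmonic mean of precision and recall
#'
#' Scale-equivariant, so fractions and percentages both work: inputs as
#' percentages give the F-score as a percentage.
#'
#' @param precision,recall Non-negative values on a common scale.
#' @return `2 * P * R / (P + R)`, or 0 when both inputs are 0.
#' @export
f_score_from_pr <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Event-based evaluation over a file collection
#'
#' Matches predictions to ground truth per audio file, then reports
#' per-file scores and the pooled (micro-averaged) score: TP/FP/FN are
#' summed over files before computing precision/recall/F.
#'
#' @param gt Ground-truth events with `audiofilename` and `status`.
#' @param pred Predicted events with `audiofilename`.
#' @param iou_min Minimum IoU for a match.
#' @return A `sed_eval` object: list with `by_file` and `pooled` tibbles.
#' @export
evaluate_detections <- function(gt, pred, iou_min = 0.3) {
  files <- sort(unique(c(gt$audiofilename, pred$audiofilename)))
  rows <- purrr::map(files, function(f) {
    m <- match_events(gt[gt$audiofilename == f, , drop = FALSE],
                      pred[pred$audiofilename == f, , drop = FALSE],
                      iou_min = iou_min)
    dplyr::mutate(precision_recall_fscore(m$tp, m$fp, m$fn),
                  audiofilename = f, .before = 1)
  })
  by_file <- dplyr::bind_rows(rows)
  pooled <- precision_recall_fscore(sum(by_file$tp), sum(by_file$fp),
                                    sum(by_file$fn))
  structure(list(by_file = by_file, pooled = pooled, iou_min = iou_min),
            class = "sed_eval")
}

#' @export
print.sed_eval <- function(x, ...) {
  cat(sprintf("Event-based scores (IoU >= %.0f%%)\n", 100 * x$iou_min))
  print(x$by_file, n = Inf)
  cat(sprintf("Pooled: P = %.4f, R = %.4f, F = %.4f (TP %d, FP %d, FN %d)\n",
              x$pooled$precision, x$pooled$recall, x$pooled$f_score,
              x$pooled$tp, x$pooled$fp, x$pooled$fn))
  invisible(x)
}
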