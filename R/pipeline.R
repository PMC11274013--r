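#' Build a few-shot episode from an annotated file
#'
#' Implements the first-K-shots protocol: the support positives are the
#' patches inside the first `k_shot` POS events of the target class; the
#' support negatives are an equal number of patches sampled (seeded) from
#' un-annotated gaps before the K-th shot's offset; the queries are all
#' patches starting at or after that offset. The detection task is binary
#' (class 1 = target, class 2 = background).
#'
#' @param feats A `spectrogram` of the whole file (Mel + PCEN).
#' @param annotations Event tibble for this file (`label`, `status`).
#' @param enc Encoder used to embed the patches.
#' @param cfg A [detection_config()] (supplies `k_shot`).
#' @param mel_cfg The [mel_config()] used for feature extraction
#'   (supplies patch geometry).
#' @param target Target class label (default: the label of the first POS
#'   event).
#' @param seed Seed for negative-patch sampling.
#' @param keep_activations Cache last-block inputs on the episode so
#'   [tim_infer()] can fine-tune the last encoder block.
#' @return An [episode()] with extra fields: `query_info` (patch times),
#'   `shots` (the K support events), `t0` (K-th shot offset), and
#'   `pos_class = 1`.
#' @export
build_file_episode <- function(feats, annotations, enc,
                               cfg = detection_config(),
                               mel_cfg = mel_config(), target = NULL,
                               seed = 1, keep_activations = FALSE) {
  pos <- annotations |>
    dplyr::filter(.data$status == "POS") |>
    dplyr::arrange(.data$onset_s)
  if (is.null(target)) {
    if (nrow(pos) == 0) abort("no POS events to infer the target class from")
    target <- pos$label[1]
  }
  pos <- pos[pos$label == target, , drop = FALSE]
  if (nrow(pos) < cfg$k_shot) {
    abort(sprintf("need >= %d POS events of class '%s', found %d",
                  cfg$k_shot, target, nrow(pos)))
  }
  shots <- pos[seq_len(cfg$k_shot), , drop = FALSE]
  t0 <- shots$offset_s[cfg$k_shot]

  sup_pos <- unlist(lapply(seq_len(nrow(shots)), function(i) {
    patches_for_interval(feats, mel_cfg, shots$onset_s[i], shots$offset_s[i])
  }), recursive = FALSE)
  if (!length(sup_pos)) abort("no patches found inside the support shots")

  # negative support: patches wholly inside un-annotated gaps before t0
  occupied <- annotations[, c("onset_s", "offset_s")]
  all_p <- make_patches(feats, mel_cfg)
  before <- all_p$info$end_s <= t0
  clear <- vapply(seq_len(nrow(all_p$info)), function(j) {
    if (!before[j]) return(FALSE)
    s <- all_p$info$start_s[j]; e <- all_p$info$end_s[j]
    !any(pmax(occupied$onset_s, s) < pmin(occupied$offset_s, e))
  }, logical(1))
  gap_idx <- which(clear)
  if (!length(gap_idx)) {
    abort("no un-annotated gap audio before the last support shot; a longer context is required")
  }
  n_neg <- length(sup_pos)
  take <- with_seed(seed,
    gap_idx[sample.int(length(gap_idx), n_neg,
                       replace = length(gap_idx) < n_neg)])
  sup_neg <- lapply(take, function(j) {
    feats$values[all_p$info$first_frame[j]:all_p$info$last_frame[j], ,
                 drop = FALSE]
  })

  qry_sel <- which(all_p$info$start_s >= t0)
  if (!length(qry_sel)) abort("no query audio after the last support shot")
  qry <- lapply(qry_sel, function(j) {
    feats$values[all_p$info$first_frame[j]:all_p$info$last_frame[j], ,
                 drop = FALSE]
  })

  sup_patches <- c(sup_pos, sup_neg)
  sup_y <- c(rep(1L, length(sup_pos)), rep(2L, length(sup_neg)))

  if (keep_activations) {
    acts <- embed_with_activations(enc, c(sup_patches, qry))
    ep <- episode(acts$Z[seq_along(sup_y), , drop = FALSE], sup_y,
                  acts$Z[-seq_along(sup_y), , drop = FALSE], n_way = 2L)
    ns <- length(sup_y)
    hw <- acts$dims$H * acts$dims$W
    ep$support_A <- acts$A[, seq_len(ns * hw), drop = FALSE]
    ep$query_A <- acts$A[, -seq_len(ns * hw), drop = FALSE]
    ep$act_dims <- list(H = acts$dims$H, W = acts$dims$W,
                        ns = ns, nq = length(qry))
  } else {
    Zs <- embed(enc, sup_patches)
    Zq <- embed(enc, qry)
    ep <- episode(Zs, sup_y, Zq, n_way = 2L)
  }
  ep$query_info <- all_p$info[qry_sel, , drop = FALSE]
  ep$shots <- shots
  ep$t0 <- t0
  ep$pos_class <- 1L
  ep$target <- target
  ep
}

# Embeddings plus cached inputs to the last encoder block (eval mode),
# for classifier+last_block TIM.
embed_with_activations <- function(enc, patches, batch_size = 256) {
  inp <- patches_to_input(patches, enc$config$min_frames)
  li <- length(enc$blocks)
  n <- inp$N
  Z <- matrix(0, n, enc$config$embedding_dim)
  A_parts <- vector("list", ceiling(n / batch_size))
  hw <- inp$H * inp$W
  bi <- 0L
  dims <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    end <- min(start + batch_size - 1L, n)
    cols <- ((start - 1L) * hw + 1L):(end * hw)
    nb <- end - start + 1L
    part <- encoder_forward(enc, inp$X[, cols, drop = FALSE], inp$H, inp$W,
                            nb, training = FALSE, stop_before_block = li)
    dims <- list(H = part$H, W = part$W)
    fw <- encoder_forward(enc, part$A, part$H, part$W, nb, training = FALSE,
                          from_block = li)
    Z[start:end, ] <- fw$Z
    bi <- bi + 1L
    A_parts[[bi]] <- part$A
  }
  list(Z = Z, A = do.call(cbind, A_parts[seq_len(bi)]), dims = dims)
}

#' Detect events in one annotated file with TIM
#'
#' End-to-end per-file detection: load audio, compute Mel + PCEN
#' features, build the first-K-shots episode, run transductive inference,
#' map per-patch positive posteriors back to frames (overlapping patches
#' averaged), segment into events, and apply the shot-length post-filter.
#'
#' @param wav_path Path to the audio file.
#' @param ann_path Path to its annotation CSV (or an event tibble).
#' @param enc Trained encoder.
#' @param det_cfg A [detection_config()].
#' @param mel_cfg A [mel_config()].
#' @param pcen_cfg A [pcen_config()].
#' @param tim_cfg A [tim_config()] (ignored by the baseline).
#' @param target Target class (default: inferred from the annotations).
#' @param seed Seed for negative-support sampling.
#' @param system `"tim"` or `"baseline"` (nearest-prototype, no
#'   transductive iterations).
#' @return Predicted event tibble (`audiofilename`, `onset_s`,
#'   `offset_s`, `label`, `score`), with the TIM fit attached as
#'   attribute `"fit"`.
#' @export
detect_file <- function(wav_path, ann_path, enc,
                        det_cfg = detection_config(),
                        mel_cfg = mel_config(), pcen_cfg = pcen_config(),
                        tim_cfg = tim_config(), target = NULL, seed = 1,
                        system = c("tim", "baseline")) {
  system <- match.arg(system)
  w <- load_audio(wav_path, mel_cfg$sample_rate)
  feats <- pcen(mel_spectrogram(w, mel_cfg), pcen_cfg)
  ann <- if (is.character(ann_path)) read_annotations(ann_path) else ann_path
  ep <- build_file_episode(
    feats, ann, enc, cfg = det_cfg, mel_cfg = mel_cfg, target = target,
    seed = seed,
    keep_activations = system == "tim" &&
      tim_cfg$update_scope == "classifier+last_block")
  fit <- if (system == "tim") tim_infer(ep, tim_cfg, enc = enc) else proto_infer(ep)

  p_patch <- fit$posterior$P[, ep$pos_class]
  fr <- patch_scores_to_frames(p_patch, ep$query_info, nrow(feats$values))
  events <- frames_to_events(fr$probs, feats$frame_hop_s, det_cfg,
                             start_s = feats$start_time_s +
                               (fr$first_frame - 1) * feats$frame_hop_s,
                             label = ep$target)
  events <- filter_short_events(events, ep$shots, det_cfg$min_dur_frac)
  events <- dplyr::mutate(events, audiofilename = basename(wav_path),
                          .before = 1)
  attr(events, "fit") <- fit
  attr(events, "episode_t0") <- ep$t0
  events
}

#' @rdname detect_file
#' @export
baseline_detect_file <- function(wav_path, ann_path, enc,
                                 det_cfg = detection_config(),
                                 mel_cfg = mel_config(),
                                 pcen_cfg = pcen_config(), target = NULL,
                                 seed = 1) {
  detect_file(wav_path, ann_path, enc, det_cfg = det_cfg, mel_cfg = mel_cfg,
              pcen_cfg = pcen_cfg, target = target, seed = seed,
              system = "baseline")
}

# Average per-patch scores onto the frames each patch covers. Returns the
# per-frame probabilities over the contiguous query region plus the index
# of its first frame (1-based).
patch_scores_to_frames <- function(p_patch, info, n_frames) {
  f0 <- min(info$first_frame)
  f1 <- max(info$last_frame)
  acc <- numeric(f1 - f0 + 1L)
  cnt <- numeric(f1 - f0 + 1L)
  plen <- info$last_frame[1] - info$first_frame[1] + 1L
  for (o in 0:(plen - 1L)) {
    idx <- info$first_frame + o - f0 + 1L
    ok <- idx >= 1L & idx <= length(acc)
    acc[idx[ok]] <- acc[idx[ok]] + p_patch[ok]
    cnt[idx[ok]] <- cnt[idx[ok]] + 1
  }
  covered <- cnt > 0
  probs <- numeric(length(acc))
  probs[covered] <- acc[covered] / cnt[covered]
  list(probs = probs, first_frame = f0)
}
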