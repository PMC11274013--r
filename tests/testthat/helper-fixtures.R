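# Shared fixtures, generated in code and memoized per test session.

.fixtures <- new.env(parent = emptyenv())

# Gaussian-cluster episode: class centers are distinct random sign
# vectors scaled by `scale`, members N(center, sigma^2 I).
gen_cluster_episode <- function(n_way = 5, k_shot = 5, n_query = 15, d = 8,
                                scale = 3, sigma = 0.1, seed = 0) {
  set.seed(seed)
  repeat {
    centers <- matrix(sample(c(-scale, scale), n_way * d, replace = TRUE),
                      n_way, d)
    if (nrow(unique(centers)) == n_way) break
  }
  draw <- function(n) {
    do.call(rbind, lapply(seq_len(n_way), function(k) {
      matrix(rnorm(n * d, 0, sigma), n, d) +
        matrix(centers[k, ], n, d, byrow = TRUE)
    }))
  }
  list(ep = episode(draw(k_shot), rep(seq_len(n_way), each = k_shot), draw(n_query)),
       query_y = rep(seq_len(n_way), each = n_query))
}

# Toy base dataset: two classes with disjoint active band ranges plus a
# flat-noise background class, as small frames x bands patches.
toy_patch_data <- function(n_per_class = 40, H = 16, W = 32, seed = 1) {
  set.seed(seed)
  mk <- function(bands) {
    lapply(seq_len(n_per_class), function(i) {
      m <- matrix(abs(rnorm(H * W, 0.1, 0.05)), H, W)
      m[, bands] <- m[, bands] + abs(rnorm(H * length(bands), 1, 0.2))
      m
    })
  }
  patches <- c(mk(3:8), mk(20:25))
  list(patches = patches,
       labels = rep(c("low", "high"), each = n_per_class))
}

# Exhaustive matching oracle: best (cardinality, total IoU) over all
# matchings of a small IoU matrix.
brute_force_match <- function(iou, iou_min) {
  nP <- nrow(iou); nQ <- ncol(iou)
  best <- c(0, 0)
  rec <- function(i, used, card, tot) {
    if (i > nP) {
      if (card > best[1] || (card == best[1] && tot > best[2] + 1e-12)) {
        best <<- c(card, tot)
      }
      return()
    }
    rec(i + 1, used, card, tot)
    for (j in seq_len(nQ)) {
      if (!(j %in% used) && iou[i, j] >= iou_min) {
        rec(i + 1, c(used, j), card + 1, tot + iou[i, j])
      }
    }
  }
  rec(1, integer(0), 0, 0)
  best
}

# The benchmark class templates: two classes in disjoint frequency bands.
benchmark_classes <- function() {
  list(A = class_template("tone", c(1800, 2200)),
       B = class_template("chirp_up", c(5000, 7000)))
}

# Desk-scale end-to-end fixture: 4 training + 2 validation scenes at
# SNR 20 dB (validation scenes single-class), plus an encoder pre-trained
# for 10 epochs. Built once per test run.
e2e_fixture <- function() {
  if (!is.null(.fixtures$e2e)) return(.fixtures$e2e)
  dir <- file.path(tempdir(), "fewshotSED_e2e")
  cls <- benchmark_classes()
  train_cfgs <- lapply(1:4, function(i) {
    scene_config(duration_s = 30, classes = cls, events_per_class = 8,
                 snr_db = 20, seed = i)
  })
  val_cfgs <- list(
    scene_config(duration_s = 40, classes = cls["A"], events_per_class = 12,
                 snr_db = 20, seed = 101),
    scene_config(duration_s = 40, classes = cls["B"], events_per_class = 12,
                 snr_db = 20, seed = 102)
  )
  generate_dataset(dir, train_cfgs, val_cfgs, seed = 0)
  base <- build_base_dataset(file.path(dir, "Training_Set"), seed = 0)
  enc <- build_encoder(encoder_config(filters = c(8, 16, 32, 64)), seed = 0)
  enc <- pretrain(enc, base$patches, base$labels,
                  train_config(epochs = 10, seed = 0),
                  aug_cfg = augment_config())
  .fixtures$e2e <- list(dir = dir, enc = enc,
                        val_wavs = sort(list.files(
                          file.path(dir, "Validation_Set"),
                          pattern = "\\.wav$", full.names = TRUE)))
  .fixtures$e2e
}

# Ground truth restricted to the scoreable region (beyond the 5th shot).
scoreable_gt <- function(csv, k_shot = 5) {
  ann <- read_annotations(csv)
  pos <- ann[ann$status == "POS", ]
  ann[ann$onset_s >= pos$offset_s[k_shot], ]
}
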