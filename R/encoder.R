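#' Encoder architecture configuration
#'
#' The encoder is a compact CNN: `n_blocks` blocks of 3x3 convolution,
#' batch normalization, ReLU, and 2x2 max pooling, followed by global
#' average pooling, so the embedding dimension equals the last filter
#' count. The default widths (64 to 512 over four blocks) are the
#' full-scale setting; tests and desk-scale runs use narrower widths via
#' `filters`.
#'
#' @param n_blocks Number of conv blocks (default 4).
#' @param filters Integer vector of per-block filter counts.
#' @param min_frames Minimum patch frames the pooling stack requires;
#'   shorter patches are tiled up to this length before encoding.
#' @return An `encoder_config` list with `embedding_dim`.
#' @export
encoder_config <- function(n_blocks = 4, filters = c(64, 128, 256, 512),
                           min_frames = 2^n_blocks) {
  if (!is_scalar_int(n_blocks) || n_blocks < 1) abort("`n_blocks` must be a positive integer")
  filters <- as.integer(filters)
  if (length(filters) != n_blocks || any(filters < 1)) {
    abort("`filters` must give one positive count per block")
  }
  structure(list(n_blocks = as.integer(n_blocks), filters = filters,
                 min_frames = as.integer(min_frames),
                 embedding_dim = filters[n_blocks]),
            class = "encoder_config")
}

#' Training configuration for encoder pre-training
#'
#' Defaults follow the standard supervised recipe: Adam at an initial
#' learning rate of 1e-3, halved (`scheduler_gamma = 0.5`) every
#' `scheduler_step = 5` epochs, batch size 64. The prototypical baseline
#' uses its own recipe; see [baseline_train_config()].
#'
#' @param lr Initial learning rate.
#' @param scheduler_gamma Multiplicative decay factor in (0, 1].
#' @param scheduler_step Epochs between learning-rate decays.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (the useful range is 5 to 30).
#' @param seed Integer seed for parameter shuffling and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, scheduler_gamma = 0.5, scheduler_step = 5,
                         batch_size = 64, epochs = 20, seed = 1) {
  stopifnot_scalar_num(lr, "lr", 0, strict_lower = TRUE)
  stopifnot_scalar_num(scheduler_gamma, "scheduler_gamma", 0, 1, strict_lower = TRUE)
  stopifnot_scalar_num(scheduler_step, "scheduler_step", 1)
  stopifnot_scalar_num(batch_size, "batch_size", 1)
  stopifnot_scalar_num(epochs, "epochs", 1)
  structure(list(lr = lr, scheduler_gamma = scheduler_gamma,
                 scheduler_step = as.integer(scheduler_step),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Training configuration for the prototypical baseline encoder
#'
#' The baseline system trains episodically with Adam at 1e-4, decaying by
#' 0.5 every 10 epochs.
#'
#' @inheritParams train_config
#' @param n_way,k_shot,n_query Episode shape drawn per training step.
#' @param episodes_per_epoch Episodes sampled per epoch.
#' @return A `train_config` with episodic fields set.
#' @export
baseline_train_config <- function(lr = 1e-4, scheduler_gamma = 0.5,
                                  scheduler_step = 10, epochs = 20, seed = 1,
                                  n_way = 5, k_shot = 5, n_query = 5,
                                  episodes_per_epoch = 20) {
  cfg <- train_config(lr = lr, scheduler_gamma = scheduler_gamma,
                      scheduler_step = scheduler_step, batch_size = 64,
                      epochs = epochs, seed = seed)
  cfg$n_way <- as.integer(n_way)
  cfg$k_shot <- as.integer(k_shot)
  cfg$n_query <- as.integer(n_query)
  cfg$episodes_per_epoch <- as.integer(episodes_per_epoch)
  cfg
}

#' Learning rate in effect for a given epoch
#'
#' `lr * scheduler_gamma ^ floor((epoch - 1) / scheduler_step)` for a
#' 1-based epoch: with step 5 and gamma 0.5, epochs 1-5 run at `lr`,
#' 6-10 at `lr / 2`, 11-15 at `lr / 4`.
#'
#' @param cfg A [train_config()].
#' @param epoch 1-based epoch number.
#' @return The learning rate.
#' @export
scheduled_lr <- function(cfg, epoch) {
  cfg$lr * cfg$scheduler_gamma^floor((epoch - 1) / cfg$scheduler_step)
}

#' Build a randomly initialized encoder
#'
#' Conv weights use He initialization; batch-norm scale/shift start at
#' 1/0 with unit running variance. The same seed always yields the same
#' parameters.
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed for initialization.
#' @return An `encoder` object.
#' @export
build_encoder <- function(cfg = encoder_config(), seed = 1) {
  blocks <- with_seed(seed, {
    c_in <- 1L
    lapply(seq_len(cfg$n_blocks), function(i) {
      c_out <- cfg$filters[i]
      W <- matrix(rnorm(c_out * 9L * c_in, sd = sqrt(2 / (9 * c_in))),
                  nrow = c_out)
      b <- list(W = W, b = numeric(c_out),
                gamma = rep(1, c_out), beta = numeric(c_out),
                running_mean = numeric(c_out), running_var = rep(1, c_out),
                c_in = c_in, c_out = c_out)
      c_in <<- c_out
      b
    })
  })
  structure(list(blocks = blocks, config = cfg, head = NULL,
                 head_classes = NULL),
            class = "encoder")
}

#' @export
print.encoder <- function(x, ...) {
  cat(sprintf("<encoder> %d blocks (%s), embedding dim %d\n",
              x$config$n_blocks, paste(x$config$filters, collapse = "-"),
              x$config$embedding_dim))
  invisible(x)
}

# Stack a list of frames x bands matrices into the internal [1, H*W*N]
# layout, tiling each patch to at least cfg$min_frames frames.
patches_to_input <- function(patches, min_frames) {
  if (is.array(patches) && length(dim(patches)) == 3) {
    patches <- lapply(seq_len(dim(patches)[1]), function(i) patches[i, , ])
  }
  if (!length(patches)) abort("no patches supplied")
  patches <- lapply(patches, function(p) {
    if (nrow(p) < min_frames) tile_frames(p, min_frames) else p
  })
  dims <- vapply(patches, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all patches must have the same shape")
  }
  H <- dims[1, 1]; W <- dims[2, 1]
  list(X = matrix(unlist(patches, use.names = FALSE), nrow = 1),
       H = H, W = W, N = length(patches))
}

# Forward pass through all blocks. Returns embeddings [N, d] and, when
# keep_cache, everything backward needs. `training` switches batch-norm
# between batch statistics (updating running stats in `enc`) and running
# statistics.
encoder_forward <- function(enc, X, H, W, N, training = FALSE,
                            keep_cache = FALSE, stop_before_block = NULL,
                            from_block = 1L) {
  caches <- if (keep_cache) vector("list", length(enc$blocks)) else NULL
  h <- H; w <- W
  for (i in seq.int(from_block, length(enc$blocks))) {
    if (!is.null(stop_before_block) && i == stop_before_block) {
      return(list(A = X, H = h, W = w, N = N, enc = enc))
    }
    bl <- enc$blocks[[i]]
    if (h < 2 || w < 2) {
      abort(sprintf("input too small for block %d pooling (%d x %d); need patches of >= %d frames",
                    i, h, w, enc$config$min_frames))
    }
    cv <- conv_forward(X, bl$W, bl$b, h, w, bl$c_in, N)
    bn <- bn_forward(cv$Y, bl$gamma, bl$beta, bl$running_mean, bl$running_var,
                     training = training)
    if (training) {
      enc$blocks[[i]]$running_mean <- bn$running_mean
      enc$blocks[[i]]$running_var <- bn$running_var
    }
    rl <- relu_forward(bn$Y)
    pl <- pool_forward(rl$Y, h, w, N)
    if (keep_cache) {
      caches[[i]] <- list(conv_M = cv$M, bn = bn, relu = rl, pool = pl,
                          H = h, W = w)
    }
    X <- pl$Y
    h <- pl$H2; w <- pl$W2
  }
  Z <- t(gap_forward(X, h, w, N)) # [N, d]
  list(Z = Z, caches = caches, final_H = h, final_W = w, N = N, enc = enc)
}

# Backward from dZ [N, d] through all blocks; returns per-block gradients.
encoder_backward <- function(enc, fw, dZ, training = TRUE) {
  h <- fw$final_H; w <- fw$final_W; N <- fw$N
  dX <- gap_backward(t(dZ), h, w, N)
  grads <- vector("list", length(enc$blocks))
  names(grads) <- paste0("block", seq_along(enc$blocks))
  for (i in rev(seq_along(enc$blocks))) {
    bl <- enc$blocks[[i]]
    ca <- fw$caches[[i]]
    dX <- pool_backward(dX, ca$pool, bl$c_out, ca$H, ca$W, N)
    dX <- relu_backward(dX, ca$relu)
    bnb <- bn_backward(dX, ca$bn, bl$gamma, training = training)
    cvb <- conv_backward(bnb$dX, ca$conv_M, bl$W, ca$H, ca$W, bl$c_in, N)
    grads[[i]] <- list(W = cvb$dW, b = cvb$db,
                       gamma = bnb$dgamma, beta = bnb$dbeta)
    dX <- cvb$dX
  }
  grads
}

#' Embed spectrogram patches
#'
#' Runs patches through the encoder in evaluation mode (batch norm uses
#' running statistics), in mini-batches. Row `i` of the result is the
#' embedding of patch `i`.
#'
#' @param enc An `encoder`.
#' @param patches List of frames x bands matrices, or a patch x frame x
#'   band array (as from [make_patches()]).
#' @param batch_size Patches per forward batch.
#' @return Matrix `[n, embedding_dim]`.
#' @export
embed <- function(enc, patches, batch_size = 256) {
  inp <- patches_to_input(patches, enc$config$min_frames)
  n <- inp$N
  d <- enc$config$embedding_dim
  Z <- matrix(0, n, d)
  hw <- inp$H * inp$W
  for (start in seq(1L, n, by = batch_size)) {
    end <- min(start + batch_size - 1L, n)
    cols <- ((start - 1L) * hw + 1L):(end * hw)
    Xb <- inp$X[, cols, drop = FALSE]
    fw <- encoder_forward(enc, Xb, inp$H, inp$W, end - start + 1L,
                          training = FALSE)
    Z[start:end, ] <- fw$Z
  }
  Z
}

encoder_params <- function(enc, with_head = TRUE) {
  p <- lapply(enc$blocks, function(b) b[c("W", "b", "gamma", "beta")])
  names(p) <- paste0("block", seq_along(enc$blocks))
  if (with_head && !is.null(enc$head)) p$head <- enc$head
  p
}

encoder_set_params <- function(enc, params) {
  for (i in seq_along(enc$blocks)) {
    nm <- paste0("block", i)
    enc$blocks[[i]][c("W", "b", "gamma", "beta")] <- params[[nm]]
  }
  if (!is.null(params$head)) enc$head <- params$head
  enc
}

#' Pre-train the encoder with supervised classification
#'
#' Plain mini-batch training of the encoder plus a linear classification
#' head on labeled base-class patches, with softmax cross-entropy, Adam,
#' and a step learning-rate schedule. SpecAugment is applied to each
#' training patch when `aug_cfg` is given.
#'
#' @param enc An `encoder` from [build_encoder()].
#' @param patches List (or 3-D array) of frames x bands patches.
#' @param labels Class labels, one per patch (>= 2 distinct classes).
#' @param cfg A [train_config()].
#' @param aug_cfg Optional [augment_config()] applied to training patches;
#'   `NULL` disables augmentation.
#' @return The trained `encoder`, with `$loss_history` (mean loss per
#'   epoch) and `$head_classes` attached.
#' @export
pretrain <- function(enc, patches, labels, cfg = train_config(),
                     aug_cfg = NULL) {
  if (is.array(patches) && length(dim(patches)) == 3) {
    patches <- lapply(seq_len(dim(patches)[1]), function(i) patches[i, , ])
  }
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) abort("pre-training needs >= 2 base classes")
  y <- match(as.character(labels), classes)
  K <- length(classes)
  d <- enc$config$embedding_dim

  with_seed(cfg$seed, {
    enc$head <- list(W = matrix(rnorm(K * d, sd = 0.01), K, d),
                     b = numeric(K))
    params <- encoder_params(enc)
    opt <- adam_init(params)
    losses <- numeric(cfg$epochs)
    n <- length(patches)
    for (epoch in seq_len(cfg$epochs)) {
      lr <- scheduled_lr(cfg, epoch)
      ord <- sample.int(n)
      epoch_loss <- 0; n_batches <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        pb <- patches[idx]
        if (!is.null(aug_cfg)) {
          pb <- lapply(pb, function(p) {
            augment(tile_frames(p, enc$config$min_frames), aug_cfg)
          })
        }
        inp <- patches_to_input(pb, enc$config$min_frames)
        fw <- encoder_forward(enc, inp$X, inp$H, inp$W, inp$N,
                              training = TRUE, keep_cache = TRUE)
        enc <- fw$enc # running stats updated
        logits <- fw$Z %*% t(enc$head$W) + rep(enc$head$b, each = inp$N)
        ce <- softmax_ce(logits, y[idx])
        dZ <- ce$dlogits %*% enc$head$W
        grads <- encoder_backward(enc, fw, dZ)
        grads$head <- list(W = t(ce$dlogits) %*% fw$Z, b = colSums(ce$dlogits))
        params <- encoder_params(enc)
        st <- adam_step(params, grads, opt, lr)
        opt <- st$state
        enc <- encoder_set_params(enc, st$params)
        epoch_loss <- epoch_loss + ce$loss
        n_batches <- n_batches + 1L
      }
      losses[epoch] <- epoch_loss / n_batches
    }
    enc$loss_history <- losses
    enc$head_classes <- classes
    enc
  })
}

#' Pre-train the encoder with prototypical episodes
#'
#' Episodic training used by the prototypical baseline: each step samples
#' an N-way K-shot episode from the base classes, computes class
#' prototypes from the support embeddings, classifies the queries by
#' softmax over negative squared Euclidean distance to the prototypes,
#' and backpropagates the query cross-entropy.
#'
#' @inheritParams pretrain
#' @param cfg A [baseline_train_config()].
#' @return The trained `encoder` with `$loss_history`.
#' @export
pretrain_protonet <- function(enc, patches, labels,
                              cfg = baseline_train_config(), aug_cfg = NULL) {
  if (is.array(patches) && length(dim(patches)) == 3) {
    patches <- lapply(seq_len(dim(patches)[1]), function(i) patches[i, , ])
  }
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) abort("pre-training needs >= 2 base classes")
  y <- match(as.character(labels), classes)
  by_class <- split(seq_along(y), y)

  with_seed(cfg$seed, {
    params <- encoder_params(enc, with_head = FALSE)
    opt <- adam_init(params)
    losses <- numeric(cfg$epochs)
    n_way <- min(cfg$n_way, length(classes))
    for (epoch in seq_len(cfg$epochs)) {
      lr <- scheduled_lr(cfg, epoch)
      ep_loss <- 0
      for (e in seq_len(cfg$episodes_per_epoch)) {
        cls <- sample(seq_along(by_class), n_way)
        sup_idx <- integer(0); qry_idx <- integer(0); qry_y <- integer(0)
        for (ci in seq_along(cls)) {
          pool <- by_class[[cls[ci]]]
          size <- cfg$k_shot + cfg$n_query
          take <- pool[sample.int(length(pool), size,
                                  replace = length(pool) < size)]
          sup_idx <- c(sup_idx, take[seq_len(cfg$k_shot)])
          qq <- take[-seq_len(cfg$k_shot)]
          qry_idx <- c(qry_idx, qq)
          qry_y <- c(qry_y, rep(ci, length(qq)))
        }
        all_idx <- c(sup_idx, qry_idx)
        pb <- patches[all_idx]
        if (!is.null(aug_cfg)) {
          pb <- lapply(pb, function(p) {
            augment(tile_frames(p, enc$config$min_frames), aug_cfg)
          })
        }
        inp <- patches_to_input(pb, enc$config$min_frames)
        fw <- encoder_forward(enc, inp$X, inp$H, inp$W, inp$N,
                              training = TRUE, keep_cache = TRUE)
        enc <- fw$enc
        ns <- length(sup_idx)
        Zs <- fw$Z[seq_len(ns), , drop = FALSE]
        Zq <- fw$Z[-seq_len(ns), , drop = FALSE]
        sup_y <- rep(seq_len(n_way), each = cfg$k_shot)
        proto <- rowsum(Zs, sup_y) / as.vector(table(sup_y))
        dd <- sq_dist(Zq, proto)
        ce <- softmax_ce(-dd, qry_y)
        # d(-||z-c||^2)/dz = -2 (z - c); dlogits flows to queries and,
        # through the prototype means, back to the support embeddings
        nq <- nrow(Zq)
        dZq <- matrix(0, nq, ncol(Zq))
        dproto <- matrix(0, n_way, ncol(Zq))
        for (k in seq_len(n_way)) {
          diff <- Zq - matrix(proto[k, ], nq, ncol(Zq), byrow = TRUE)
          dZq <- dZq + ce$dlogits[, k] * (-2) * diff
          dproto[k, ] <- colSums(ce$dlogits[, k] * 2 * diff)
        }
        dZs <- dproto[sup_y, , drop = FALSE] / cfg$k_shot
        dZ <- rbind(dZs, dZq)
        grads <- encoder_backward(enc, fw, dZ)
        params <- encoder_params(enc, with_head = FALSE)
        st <- adam_step(params, grads, opt, lr)
        opt <- st$state
        enc <- encoder_set_params(enc, st$params)
        ep_loss <- ep_loss + ce$loss
      }
      losses[epoch] <- ep_loss / cfg$episodes_per_epoch
    }
    enc$loss_history <- losses
    enc
  })
}

# squared Euclidean distances between rows of A [n, d] and B [m, d]
sq_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  outer(an, bn, "+") - 2 * A %*% t(B)
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint embeds a hash of the architecture config; loading warns
#' if a different config produced the file.
#'
#' @param enc An `encoder`.
#' @param path Checkpoint file path.
#' @return `path` / the restored `encoder`.
#' @export
save_encoder <- function(enc, path) {
  obj <- list(encoder = enc, config_hash = config_hash(enc$config),
              format_version = 1L)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) abort("unknown checkpoint format")
  if (!identical(config_hash(obj$encoder$config), obj$config_hash)) {
    warn("checkpoint config hash mismatch; file may be corrupt")
  }
  obj$encoder
}
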