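test_that("encoder shape contract: embedding dim equals last filter count", {
  enc <- build_encoder(encoder_config(), seed = 1)
  z <- embed(enc, list(matrix(rnorm(17 * 128), 17, 128)))
  expect_equal(dim(z), c(1, 512))
  expect_true(all(is.finite(z)))

  enc2 <- build_encoder(encoder_config(n_blocks = 2, filters = c(4, 8),
                                       min_frames = 4), seed = 1)
  z2 <- embed(enc2, list(matrix(0, 8, 8)))
  expect_equal(ncol(z2), 8)
  expect_true(all(is.finite(z2))) # all-zero input, fresh normalization
})

test_that("initialization and embedding are deterministic and batch-equivariant", {
  cfg <- encoder_config(n_blocks = 2, filters = c(4, 8), min_frames = 4)
  e1 <- build_encoder(cfg, seed = 9)
  e2 <- build_encoder(cfg, seed = 9)
  expect_identical(e1$blocks, e2$blocks)
  expect_false(identical(build_encoder(cfg, seed = 10)$blocks, e1$blocks))

  set.seed(4)
  ps <- lapply(1:6, function(i) matrix(runif(8 * 8), 8, 8))
  Z <- embed(e1, ps)
  expect_equal(nrow(Z), 6)
  expect_equal(Z[2, ], embed(e1, ps[c(2, 2)])[1, ]) # duplicates embed alike
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(embed(e1, ps[perm]), Z[perm, ], tolerance = 1e-12)
  expect_error(embed(e1, list(matrix(0, 8, 8), matrix(0, 8, 10))), "same shape")
})

test_that("backpropagation matches finite differences", {
  ns <- asNamespace("fewshotSED")
  set.seed(2)
  enc <- build_encoder(encoder_config(n_blocks = 2, filters = c(3, 4),
                                      min_frames = 4), seed = 3)
  patches <- lapply(1:6, function(i) matrix(runif(7 * 9), 7, 9)) # odd dims
  y <- rep(1:2, 3)
  inp <- ns$patches_to_input(patches, 4)
  enc$head <- list(W = matrix(rnorm(2 * 4, sd = 0.1), 2, 4),
                   b = rnorm(2, sd = 0.1))
  loss_fn <- function(e) {
    fw <- ns$encoder_forward(e, inp$X, inp$H, inp$W, inp$N,
                             training = TRUE, keep_cache = TRUE)
    logits <- fw$Z %*% t(e$head$W) + rep(e$head$b, each = inp$N)
    ns$softmax_ce(logits, y)$loss
  }
  fw <- ns$encoder_forward(enc, inp$X, inp$H, inp$W, inp$N,
                           training = TRUE, keep_cache = TRUE)
  logits <- fw$Z %*% t(enc$head$W) + rep(enc$head$b, each = inp$N)
  ce <- ns$softmax_ce(logits, y)
  grads <- ns$encoder_backward(enc, fw, ce$dlogits %*% enc$head$W)

  eps <- 1e-6
  for (spec in list(list("W", 1), list("W", 2), list("gamma", 1),
                    list("beta", 2), list("b", 1))) {
    nm <- spec[[1]]; bi <- spec[[2]]
    v <- enc$blocks[[bi]][[nm]]
    idx <- sample(length(v), min(4, length(v)))
    num <- vapply(idx, function(k) {
      e1 <- enc; e1$blocks[[bi]][[nm]][k] <- e1$blocks[[bi]][[nm]][k] + eps
      e2 <- enc; e2$blocks[[bi]][[nm]][k] <- e2$blocks[[bi]][[nm]][k] - eps
      (loss_fn(e1) - loss_fn(e2)) / (2 * eps)
    }, numeric(1))
    ana <- grads[[paste0("block", bi)]][[nm]][idx]
    expect_lt(max(abs(num - ana) / (abs(num) + 1e-6)), 1e-4)
  }
})

test_that("the learning-rate schedule decays stepwise", {
  cfg <- train_config(lr = 1e-3, scheduler_gamma = 0.5, scheduler_step = 5)
  expect_equal(scheduled_lr(cfg, 1), 1e-3)
  expect_equal(scheduled_lr(cfg, 5), 1e-3)
  expect_equal(scheduled_lr(cfg, 6), 5e-4)
  expect_equal(scheduled_lr(cfg, 11), 2.5e-4) # after 10 completed epochs
})

test_that("supervised pre-training separates two disjoint-band classes", {
  toy <- toy_patch_data(n_per_class = 100)
  enc <- build_encoder(encoder_config(n_blocks = 2, filters = c(4, 8)),
                       seed = 0)
  cfg <- train_config(epochs = 5, batch_size = 16, seed = 0)
  enc <- pretrain(enc, toy$patches, toy$labels, cfg)
  expect_length(enc$loss_history, 5)
  expect_lt(enc$loss_history[5], enc$loss_history[1])

  # training accuracy via the learned head
  Z <- embed(enc, toy$patches)
  logits <- Z %*% t(enc$head$W) + rep(enc$head$b, each = nrow(Z))
  pred <- enc$head_classes[max.col(logits)]
  expect_gte(mean(pred == toy$labels), 0.95)

  expect_error(pretrain(enc, toy$patches, rep("one", length(toy$patches)), cfg),
               "2 base classes")
})

test_that("seeded pre-training is reproducible", {
  toy <- toy_patch_data(n_per_class = 10)
  run <- function() {
    enc <- build_encoder(encoder_config(n_blocks = 2, filters = c(3, 4)),
                         seed = 1)
    pretrain(enc, toy$patches, toy$labels,
             train_config(epochs = 2, batch_size = 8, seed = 5),
             aug_cfg = augment_config(t_max = 2, f_max = 3, warp_w = 2))
  }
  e1 <- run(); e2 <- run()
  expect_identical(e1$loss_history, e2$loss_history)
  expect_equal(embed(e1, toy$patches[1:3]), embed(e2, toy$patches[1:3]))
})

test_that("prototypical episodic pre-training reduces its loss", {
  toy <- toy_patch_data(n_per_class = 25)
  enc <- build_encoder(encoder_config(n_blocks = 2, filters = c(4, 8)),
                       seed = 0)
  cfg <- baseline_train_config(lr = 1e-4, epochs = 4, n_way = 2, k_shot = 5,
                               n_query = 5, episodes_per_epoch = 10, seed = 0)
  enc <- pretrain_protonet(enc, toy$patches, toy$labels, cfg)
  expect_length(enc$loss_history, 4)
  expect_lt(enc$loss_history[4], enc$loss_history[1])
})

test_that("encoder checkpoints reload to identical embeddings", {
  f <- withr::local_tempfile(fileext = ".rds")
  enc <- build_encoder(encoder_config(n_blocks = 2, filters = c(3, 4)),
                       seed = 2)
  save_encoder(enc, f)
  enc2 <- load_encoder(f)
  p <- list(matrix(runif(16 * 16), 16, 16))
  expect_identical(embed(enc, p), embed(enc2, p))
})
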