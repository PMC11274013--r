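test_that("prototypes are support means", {
  ep <- episode(matrix(c(0, 0, 2, 0, 0, 4), 3, 2, byrow = TRUE),
                c(1, 1, 2),
                matrix(rnorm(4), 2, 2))
  W <- init_prototypes(ep)$W
  expect_equal(W, matrix(c(1, 0, 0, 4), 2, 2, byrow = TRUE))

  # 1-shot: the prototype is the single support vector
  ep1 <- episode(matrix(1:4, 2, 2), 1:2, matrix(0, 1, 2))
  expect_equal(init_prototypes(ep1)$W, matrix(1:4, 2, 2) + 0)

  # duplicated support vectors leave the prototype unchanged
  ep2 <- episode(rbind(c(1, 2), c(1, 2), c(5, 5)), c(1, 1, 2),
                 matrix(0, 1, 2))
  expect_equal(init_prototypes(ep2)$W[1, ], c(1, 2))

  expect_error(episode(matrix(1:4, 2, 2), c(1, 1), matrix(0, 1, 2), n_way = 2),
               "no support")
})

test_that("the posterior is a stable inner-product softmax", {
  Z <- matrix(rnorm(12), 6, 2)
  pm <- posterior(matrix(0, 3, 2), Z) # zero logits -> uniform
  expect_equal(pm$P, matrix(1 / 3, 6, 3), ignore_attr = TRUE)

  # K = 2 with logits (1, 0)
  pm2 <- posterior(rbind(c(1, 0), c(0, 0)), matrix(c(1, 0), 1, 2))
  expect_equal(pm2$P[1, ], c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)

  # rows sum to 1 and the marginal is the column mean
  set.seed(8)
  for (i in 1:25) {
    W <- matrix(rnorm(8), 4, 2) * 10
    pm <- posterior(W, matrix(rnorm(20), 10, 2) * 10)
    expect_equal(rowSums(pm$P), rep(1, 10), tolerance = 1e-9)
    expect_equal(pm$marginal, colMeans(pm$P), tolerance = 1e-12)
  }
  # extreme logits stay finite (max subtraction)
  pm3 <- posterior(matrix(c(1000, -1000), 2, 1), matrix(1, 1, 1))
  expect_true(all(is.finite(pm3$P)))
})

test_that("mutual information matches its definition and bounds", {
  expect_equal(mutual_information(matrix(0.25, 7, 4)), 0)
  onehot <- diag(4)[rep(1:4, 5), ]
  expect_equal(mutual_information(onehot), log(4))

  # brute-force double-sum oracle
  brute_mi <- function(P) {
    phat <- colMeans(P)
    tot <- 0
    for (k in seq_len(ncol(P))) {
      if (phat[k] > 0) tot <- tot - phat[k] * log(phat[k])
    }
    for (i in seq_len(nrow(P))) {
      for (k in seq_len(ncol(P))) {
        if (P[i, k] > 0) tot <- tot + P[i, k] * log(P[i, k]) / nrow(P)
      }
    }
    tot
  }
  set.seed(11)
  for (t in 1:200) {
    K <- sample(2:6, 1); n <- sample(1:10, 1)
    P <- matrix(rexp(n * K), n, K)
    P <- P / rowSums(P)
    I <- mutual_information(P)
    expect_lt(abs(I - brute_mi(P)), 1e-10)
    expect_gte(I, 0)
    expect_lte(I, log(K) + 1e-12)
  }
  expect_error(mutual_information(matrix(numeric(0), 0, 2)), "empty")
})

test_that("support cross-entropy matches hand evaluation", {
  # saturated correct posteriors give ~0
  Zs <- 100 * diag(2)
  ep <- episode(Zs, 1:2, matrix(0, 1, 2))
  cs <- init_prototypes(ep)
  expect_lt(support_cross_entropy(cs, ep), 1e-8)

  # uniform posterior gives log K
  ep0 <- episode(matrix(0, 3, 2), c(1, 2, 3), matrix(0, 1, 2), n_way = 3)
  expect_equal(support_cross_entropy(structure(list(W = matrix(0, 3, 2)),
                                               class = "classifier_state"),
                                     ep0), log(3))

  # true-label probabilities 0.8 and 0.5 give CE = 0.4581
  W <- diag(2)
  Zs2 <- rbind(c(log(4), 0), c(0, 0))
  ep2 <- list(support_Z = Zs2, support_y = c(1L, 1L)) # bare support view
  cs2 <- structure(list(W = W), class = "classifier_state")
  p <- posterior(cs2, Zs2)$P
  expect_equal(p[cbind(1:2, c(1, 1))], c(0.8, 0.5))
  expect_equal(support_cross_entropy(cs2, ep2),
               -(log(0.8) + log(0.5)) / 2)
  expect_equal(-(log(0.8) + log(0.5)) / 2, 0.4581, tolerance = 1e-4)
})

test_that("the TIM loss composes cross-entropy and mutual information", {
  set.seed(13)
  ep <- gen_cluster_episode(3, 4, 6, 5, scale = 1, sigma = 1, seed = 13)$ep
  cs <- init_prototypes(ep)
  expect_equal(tim_loss(cs, ep, tim_config(lambda_ce = 0)),
               -mutual_information(posterior(cs, ep$query_Z)))
  expect_equal(tim_loss(cs, ep, tim_config(lambda_ce = 1)),
               support_cross_entropy(cs, ep) -
                 mutual_information(posterior(cs, ep$query_Z)))
  expect_equal(tim_loss(cs, ep, tim_config(lambda_ce = 2.5)),
               2.5 * support_cross_entropy(cs, ep) -
                 mutual_information(posterior(cs, ep$query_Z)))

  # saturated correct posteriors, balanced K = 4 queries: loss ~ -log 4
  Zb <- 100 * diag(4)
  epb <- episode(Zb, 1:4, Zb[rep(1:4, 3), ])
  expect_equal(tim_loss(init_prototypes(epb), epb), -log(4), tolerance = 1e-6)
})

test_that("the analytic TIM gradient matches finite differences", {
  ns <- asNamespace("fewshotSED")
  set.seed(14)
  ep <- gen_cluster_episode(3, 3, 5, 4, scale = 1, sigma = 1, seed = 14)$ep
  W <- init_prototypes(ep)$W
  g <- ns$tim_grad(W, ep, 1)$dW
  cfg <- tim_config()
  eps <- 1e-6
  num <- W * 0
  for (i in seq_along(W)) {
    W1 <- W; W1[i] <- W1[i] + eps
    W2 <- W; W2[i] <- W2[i] - eps
    num[i] <- (tim_loss(structure(list(W = W1), class = "classifier_state"), ep, cfg) -
                 tim_loss(structure(list(W = W2), class = "classifier_state"), ep, cfg)) /
      (2 * eps)
  }
  expect_lt(max(abs(num - g)), 1e-8)
})

test_that("TIM solves well-separated episodes with a descending loss", {
  g <- gen_cluster_episode(n_way = 5, k_shot = 5, n_query = 15, d = 8,
                           scale = 3, sigma = 0.1, seed = 0)
  fit <- tim_infer(g$ep)
  expect_equal(mean(fit$predicted == g$query_y), 1.0)
  expect_true(all(diff(fit$trace) <= 1e-6))
})

test_that("a 1-way episode needs no iterations", {
  ep <- episode(matrix(rnorm(6), 3, 2), rep(1, 3), matrix(rnorm(8), 4, 2),
                n_way = 1)
  fit <- tim_infer(ep)
  expect_equal(fit$posterior$P, matrix(1, 4, 1))
  expect_equal(fit$n_iters, 0L)
})

test_that("transductive refinement does not fall below its prototype start", {
  res <- vapply(1:50, function(s) {
    g <- gen_cluster_episode(n_way = 5, k_shot = 5, n_query = 15, d = 8,
                             scale = 1, sigma = 1.0, seed = s)
    zero <- max.col(posterior(init_prototypes(g$ep), g$ep$query_Z)$P,
                    ties.method = "first")
    c(tim = mean(tim_infer(g$ep)$predicted == g$query_y),
      zero = mean(zero == g$query_y))
  }, numeric(2))
  expect_gte(mean(res["tim", ]), mean(res["zero", ]))
})

test_that("tidy and glance summarize a fit", {
  g <- gen_cluster_episode(3, 3, 6, 4, seed = 1)
  fit <- tim_infer(g$ep)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(g$ep$query_Z))
  expect_true(all(c("predicted", "p_1", "p_3") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_way, 3)
  expect_gte(gl$mutual_information, 0)
})
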