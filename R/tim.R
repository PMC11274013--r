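#' Construct a few-shot episode
#'
#' An episode bundles labeled support embeddings with unlabeled query
#' embeddings for one K-way task. Every class `1..n_way` must appear in
#' the support set.
#'
#' @param support_Z Support embeddings, `[|S|, d]`.
#' @param support_y Integer support labels in `1..n_way`.
#' @param query_Z Query embeddings, `[|Q|, d]`.
#' @param n_way Number of classes (default: `max(support_y)`).
#' @return An `episode` object.
#' @export
episode <- function(support_Z, support_y, query_Z, n_way = max(support_y)) {
  support_Z <- as.matrix(support_Z)
  query_Z <- as.matrix(query_Z)
  support_y <- as.integer(support_y)
  if (nrow(support_Z) != length(support_y)) {
    abort("support_Z rows must match support_y length")
  }
  if (ncol(query_Z) != ncol(support_Z)) {
    abort("support and query embedding dimensions differ")
  }
  if (nrow(query_Z) < 1) abort("episode needs at least one query")
  missing <- setdiff(seq_len(n_way), unique(support_y))
  if (length(missing)) {
    abort(sprintf("class(es) %s have no support examples",
                  paste(missing, collapse = ", ")))
  }
  counts <- tabulate(support_y, n_way)
  structure(list(support_Z = support_Z, support_y = support_y,
                 query_Z = query_Z, n_way = as.integer(n_way),
                 k_shot = min(counts)),
            class = "episode")
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf("<episode> %d-way, %d support / %d query, d = %d\n",
              x$n_way, nrow(x$support_Z), nrow(x$query_Z), ncol(x$support_Z)))
  invisible(x)
}

#' TIM inference configuration
#'
#' @param lambda_ce Weight on the support cross-entropy term (the
#'   reference setting is 1).
#' @param n_iters Maximum gradient steps on the classifier.
#' @param lr Adam step size.
#' @param tol Relative loss-change threshold for early stopping.
#' @param update_scope `"classifier_only"` (default: the backbone stays
#'   frozen and only the prototype weights move) or
#'   `"classifier+last_block"` (the last encoder block is fine-tuned
#'   jointly; requires an episode built with cached activations, see
#'   [build_file_episode()]).
#' @param optimizer `"gd"` (plain gradient descent, the default: steps
#'   scale with the gradient, so the refinement stays anchored near the
#'   prototype initialization even on heavily imbalanced query sets) or
#'   `"adam"` (adaptive-moment steps; faster drift of the query
#'   marginal towards uniform, appropriate for balanced episodes).
#' @return A `tim_config` list.
#' @export
tim_config <- function(lambda_ce = 1, n_iters = 1000, lr = 1e-3, tol = 1e-5,
                       update_scope = c("classifier_only", "classifier+last_block"),
                       optimizer = c("gd", "adam")) {
  stopifnot_scalar_num(lambda_ce, "lambda_ce", 0)
  stopifnot_scalar_num(n_iters, "n_iters", 1)
  stopifnot_scalar_num(lr, "lr", 0, strict_lower = TRUE)
  stopifnot_scalar_num(tol, "tol", 0)
  structure(list(lambda_ce = lambda_ce, n_iters = as.integer(n_iters),
                 lr = lr, tol = tol,
                 update_scope = match.arg(update_scope),
                 optimizer = match.arg(optimizer)),
            class = "tim_config")
}

#' Initialize classifier weights from class prototypes
#'
#' Row `k` of the returned weight matrix is the mean of the support
#' embeddings labeled `k`.
#'
#' @param ep An [episode()].
#' @return `classifier_state`: list with `W` (`[n_way, d]`).
#' @export
init_prototypes <- function(ep) {
  counts <- tabulate(ep$support_y, ep$n_way)
  if (any(counts == 0)) abort("every class needs at least one support example")
  W <- rowsum(ep$support_Z, ep$support_y) / counts
  structure(list(W = unname(W)), class = "classifier_state")
}

#' Posterior class probabilities under the linear classifier
#'
#' `p_ik = softmax_k( <w_k, z_i> )`, computed with max-subtraction for
#' stability. The attached `marginal` is the column mean of `P` over the
#' supplied rows — the estimated label marginal when `Z` is the query set.
#'
#' @param cs A `classifier_state` (or a bare `[K, d]` matrix).
#' @param Z Embeddings `[n, d]`.
#' @return A `posterior_matrix`: list with `P` (`[n, K]`, rows sum to 1)
#'   and `marginal` (length K).
#' @export
posterior <- function(cs, Z) {
  W <- if (is.list(cs)) cs$W else cs
  if (is.null(dim(W)) || nrow(W) < 1) abort("classifier has no classes")
  Z <- as.matrix(Z)
  if (ncol(Z) != ncol(W)) abort("embedding dimension mismatch")
  P <- softmax_rows(Z %*% t(W))
  structure(list(P = P, marginal = colMeans(P)), class = "posterior_matrix")
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Mutual information between query inputs and predicted labels
#'
#' The transductive objective's information term, in nats:
#' `I = -sum_k phat_k log phat_k + (1/|Q|) sum_i sum_k p_ik log p_ik`,
#' i.e. marginal label entropy minus mean conditional entropy, with
#' `0 log 0 = 0`. Always in `[0, log K]`.
#'
#' @param pm A `posterior_matrix` (from [posterior()]) or a row-stochastic
#'   matrix.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(pm) {
  P <- if (inherits(pm, "posterior_matrix")) pm$P else as.matrix(pm)
  if (nrow(P) < 1) abort("empty query set")
  phat <- colMeans(P)
  -sum(xlogx(phat)) + mean(rowSums(xlogx(P)))
}

#' Cross-entropy of the classifier on the support set
#'
#' Mean negative log posterior probability of the true support labels.
#' Probabilities are floored at 1e-12 so the value stays finite.
#'
#' @param cs A `classifier_state`.
#' @param ep An [episode()].
#' @return Scalar cross-entropy in nats.
#' @export
support_cross_entropy <- function(cs, ep) {
  P <- posterior(cs, ep$support_Z)$P
  p_true <- pmax(P[cbind(seq_along(ep$support_y), ep$support_y)], 1e-12)
  -mean(log(p_true))
}

#' The transductive information-maximization loss
#'
#' `L = lambda_ce * CE(support) - I(Y_Q; X_Q)`: fit the labeled shots
#' while making confident, marginally balanced predictions on the
#' unlabeled queries.
#'
#' @inheritParams support_cross_entropy
#' @param cfg A [tim_config()].
#' @return Scalar loss.
#' @export
tim_loss <- function(cs, ep, cfg = tim_config()) {
  cfg$lambda_ce * support_cross_entropy(cs, ep) -
    mutual_information(posterior(cs, ep$query_Z))
}

# Analytic gradient of tim_loss w.r.t. W, plus (optionally) the gradient
# w.r.t. the embeddings for last-block fine-tuning.
tim_grad <- function(W, ep, lambda_ce, want_dZ = FALSE) {
  Zs <- ep$support_Z; Zq <- ep$query_Z
  ns <- nrow(Zs); nq <- nrow(Zq); K <- nrow(W)

  Ps <- softmax_rows(Zs %*% t(W))
  Yoh <- matrix(0, ns, K)
  Yoh[cbind(seq_len(ns), ep$support_y)] <- 1
  dlog_s <- lambda_ce * (Ps - Yoh) / ns

  Pq <- softmax_rows(Zq %*% t(W))
  phat <- colMeans(Pq)
  # minimizing -I: dL/dp_ik = (log phat_k - log p_ik) / |Q|
  G <- (matrix(log(pmax(phat, 1e-300)), nq, K, byrow = TRUE) -
          log(pmax(Pq, 1e-300))) / nq
  dlog_q <- Pq * (G - rowSums(G * Pq))

  dW <- t(dlog_s) %*% Zs + t(dlog_q) %*% Zq
  out <- list(dW = dW)
  if (want_dZ) {
    out$dZs <- dlog_s %*% W
    out$dZq <- dlog_q %*% W
  }
  out
}

#' Transductive inference over an episode
#'
#' Initializes the classifier from the support prototypes, then runs up
#' to `cfg$n_iters` Adam steps on [tim_loss()], stopping early when the
#' relative loss change drops below `cfg$tol`. With `update_scope =
#' "classifier+last_block"` the last encoder block's conv and batch-norm
#' parameters are fine-tuned jointly (batch norm stays in evaluation
#' mode); this needs an episode carrying cached block inputs and the
#' encoder.
#'
#' @param ep An [episode()].
#' @param cfg A [tim_config()].
#' @param enc Encoder; required only for `"classifier+last_block"`.
#' @return A `tim_fit`: list with `posterior` (query `posterior_matrix`),
#'   `state` (`classifier_state`), `trace` (loss per iteration, index 1 =
#'   loss at initialization), `predicted` (query argmax labels), and
#'   `n_iters` actually run.
#' @export
tim_infer <- function(ep, cfg = tim_config(), enc = NULL) {
  if (ep$n_way == 1L) {
    P <- matrix(1, nrow(ep$query_Z), 1)
    cs <- init_prototypes(ep)
    return(structure(list(
      posterior = structure(list(P = P, marginal = 1), class = "posterior_matrix"),
      state = cs, trace = tim_loss(cs, ep, cfg), predicted = rep(1L, nrow(P)),
      n_iters = 0L), class = "tim_fit"))
  }
  if (cfg$update_scope == "classifier+last_block") {
    return(tim_infer_last_block(ep, cfg, enc))
  }
  cs <- init_prototypes(ep)
  W <- cs$W
  opt <- adam_init(list(w = list(W = W)))
  trace <- numeric(cfg$n_iters + 1L)
  trace[1] <- tim_loss(structure(list(W = W), class = "classifier_state"), ep, cfg)
  n_done <- 0L
  for (it in seq_len(cfg$n_iters)) {
    g <- tim_grad(W, ep, cfg$lambda_ce)
    if (cfg$optimizer == "gd") {
      W <- W - cfg$lr * g$dW
    } else {
      st <- adam_step(list(w = list(W = W)), list(w = list(W = g$dW)), opt, cfg$lr)
      opt <- st$state
      W <- st$params$w$W
    }
    cs <- structure(list(W = W), class = "classifier_state")
    l <- tim_loss(cs, ep, cfg)
    if (!is.finite(l)) abort(sprintf("TIM loss diverged at iteration %d", it))
    trace[it + 1L] <- l
    n_done <- it
    if (abs(trace[it + 1L] - trace[it]) < cfg$tol * max(1, abs(trace[it]))) break
  }
  trace <- trace[seq_len(n_done + 1L)]
  pq <- posterior(cs, ep$query_Z)
  structure(list(posterior = pq, state = cs, trace = trace,
                 predicted = max.col(pq$P, ties.method = "first"),
                 n_iters = n_done),
            class = "tim_fit")
}

# Joint fine-tuning of W and the last encoder block. The episode must
# carry `support_A` / `query_A`: the [C, H*W*N] inputs to the last block
# (see build_file_episode(keep_activations = TRUE)), plus `act_dims`.
tim_infer_last_block <- function(ep, cfg, enc) {
  if (is.null(enc) || is.null(ep$support_A)) {
    abort("update_scope 'classifier+last_block' needs an encoder and an episode built with keep_activations = TRUE")
  }
  li <- length(enc$blocks)
  bl <- enc$blocks[[li]]
  dims <- ep$act_dims # list(H, W, ns, nq)

  fwd_block <- function(bl, A, H, W, N) {
    cv <- conv_forward(A, bl$W, bl$b, H, W, bl$c_in, N)
    bn <- bn_forward(cv$Y, bl$gamma, bl$beta, bl$running_mean, bl$running_var,
                     training = FALSE)
    rl <- relu_forward(bn$Y)
    pl <- pool_forward(rl$Y, H, W, N)
    Z <- t(gap_forward(pl$Y, pl$H2, pl$W2, N))
    list(Z = Z, cv = cv, bn = bn, rl = rl, pl = pl, H = H, W = W, N = N)
  }
  bwd_block <- function(bl, fw, dZ) {
    dX <- gap_backward(t(dZ), fw$pl$H2, fw$pl$W2, fw$N)
    dX <- pool_backward(dX, fw$pl, bl$c_out, fw$H, fw$W, fw$N)
    dX <- relu_backward(dX, fw$rl)
    bnb <- bn_backward(dX, fw$bn, bl$gamma, training = FALSE)
    cvb <- conv_backward(bnb$dX, fw$cv$M, bl$W, fw$H, fw$W, bl$c_in, fw$N)
    list(W = cvb$dW, b = cvb$db, gamma = bnb$dgamma, beta = bnb$dbeta)
  }
  embed_now <- function(bl) {
    fs <- fwd_block(bl, ep$support_A, dims$H, dims$W, dims$ns)
    fq <- fwd_block(bl, ep$query_A, dims$H, dims$W, dims$nq)
    list(fs = fs, fq = fq)
  }

  emb <- embed_now(bl)
  ep2 <- ep; ep2$support_Z <- emb$fs$Z; ep2$query_Z <- emb$fq$Z
  W <- init_prototypes(ep2)$W

  params <- list(w = list(W = W),
                 blk = bl[c("W", "b", "gamma", "beta")])
  opt <- adam_init(params)
  loss_now <- function(W) {
    tim_loss(structure(list(W = W), class = "classifier_state"), ep2, cfg)
  }
  trace <- numeric(cfg$n_iters + 1L)
  trace[1] <- loss_now(W)
  n_done <- 0L
  for (it in seq_len(cfg$n_iters)) {
    g <- tim_grad(W, ep2, cfg$lambda_ce, want_dZ = TRUE)
    gs <- bwd_block(bl, emb$fs, g$dZs)
    gq <- bwd_block(bl, emb$fq, g$dZq)
    grads <- list(w = list(W = g$dW),
                  blk = Map(`+`, gs, gq))
    if (cfg$optimizer == "gd") {
      params <- Map(function(p, gr) Map(function(a, b) a - cfg$lr * b, p, gr),
                    params, grads)
    } else {
      st <- adam_step(params, grads, opt, cfg$lr)
      opt <- st$state
      params <- st$params
    }
    W <- params$w$W
    bl[c("W", "b", "gamma", "beta")] <- params$blk
    emb <- embed_now(bl)
    ep2$support_Z <- emb$fs$Z; ep2$query_Z <- emb$fq$Z
    l <- loss_now(W)
    if (!is.finite(l)) abort(sprintf("TIM loss diverged at iteration %d", it))
    trace[it + 1L] <- l
    n_done <- it
    if (abs(trace[it + 1L] - trace[it]) < cfg$tol * max(1, abs(trace[it]))) break
  }
  trace <- trace[seq_len(n_done + 1L)]
  cs <- structure(list(W = W), class = "classifier_state")
  pq <- posterior(cs, ep2$query_Z)
  enc$blocks[[li]] <- bl
  structure(list(posterior = pq, state = cs, trace = trace,
                 predicted = max.col(pq$P, ties.method = "first"),
                 n_iters = n_done, encoder = enc),
            class = "tim_fit")
}

#' Classify an episode's queries by nearest prototype
#'
#' The prototypical baseline's inference rule: softmax over negative
#' squared Euclidean distances to the class prototypes, with no
#' transductive iterations.
#'
#' @param ep An [episode()].
#' @return A `tim_fit`-shaped object with `posterior`, `state`,
#'   `predicted`, `n_iters = 0`.
#' @export
proto_infer <- function(ep) {
  cs <- init_prototypes(ep)
  dd <- sq_dist(ep$query_Z, cs$W)
  P <- softmax_rows(-dd)
  pq <- structure(list(P = P, marginal = colMeans(P)), class = "posterior_matrix")
  structure(list(posterior = pq, state = cs, trace = numeric(0),
                 predicted = max.col(P, ties.method = "first"), n_iters = 0L),
            class = "tim_fit")
}

#' @export
print.tim_fit <- function(x, ...) {
  cat(sprintf("<tim_fit> %d queries over %d classes, %d iterations%s\n",
              nrow(x$posterior$P), ncol(x$posterior$P), x$n_iters,
              if (length(x$trace)) sprintf(", final loss %.4f", tail(x$trace, 1)) else ""))
  invisible(x)
}
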