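# Low-level neural-network primitives.
#
# Activations are stored as a matrix X of dim [C, H*W*N]: channels in
# rows; columns enumerate spatial position (row index h fastest, then
# column w) within image, then image index n. All convolutions are 3x3,
# stride 1, zero ("same") padding; pooling is 2x2, stride 2.
# Everything reduces to BLAS matrix products via im2col, which is what
# makes a pure-R CNN viable at the patch sizes used here.

# --- im2col / col2im -------------------------------------------------------

# X [C, H*W*N] -> M [9*C, H*W*N]; row r = k + 9*(c-1) holds offset k of
# channel c, offsets enumerated dy fastest then dx (k = dy + 3*dx + 1).
nn_im2col <- function(X, H, W, C, N) {
  arr <- array(X, dim = c(C, H, W, N))
  xp <- array(0, dim = c(C, H + 2L, W + 2L, N))
  xp[, 2:(H + 1L), 2:(W + 1L), ] <- arr
  M <- matrix(0, 9L * C, H * W * N)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    S <- xp[, (1:H) + dy, (1:W) + dx, , drop = FALSE]
    M[k + 9L * (0:(C - 1L)), ] <- matrix(S, nrow = C)
  }
  M
}

nn_col2im <- function(dM, H, W, C, N) {
  gp <- array(0, dim = c(C, H + 2L, W + 2L, N))
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    G <- array(dM[k + 9L * (0:(C - 1L)), , drop = FALSE], dim = c(C, H, W, N))
    gp[, (1:H) + dy, (1:W) + dx, ] <- gp[, (1:H) + dy, (1:W) + dx, , drop = FALSE] + G
  }
  matrix(gp[, 2:(H + 1L), 2:(W + 1L), , drop = FALSE], nrow = C)
}

# --- conv ------------------------------------------------------------------

conv_forward <- function(X, Wmat, b, H, W, C, N) {
  M <- nn_im2col(X, H, W, C, N)
  Y <- Wmat %*% M + b
  list(Y = Y, M = M)
}

conv_backward <- function(dY, cache_M, Wmat, H, W, C, N) {
  dW <- dY %*% t(cache_M)
  db <- rowSums(dY)
  dM <- crossprod(Wmat, dY)
  dX <- nn_col2im(dM, H, W, C, N)
  list(dX = dX, dW = dW, db = db)
}

# --- batch norm ------------------------------------------------------------

bn_forward <- function(X, gamma, beta, running_mean, running_var,
                       training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(X)
    v <- rowMeans((X - mu)^2)
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * v
  } else {
    mu <- running_mean
    v <- running_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * invstd
  list(Y = gamma * xhat + beta, xhat = xhat, invstd = invstd,
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dY, cache, gamma, training) {
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  if (training) {
    dX <- cache$invstd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    # running statistics are constants in eval mode
    dX <- cache$invstd * dxhat
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- relu ------------------------------------------------------------------

relu_forward <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  list(Y = Y, mask = X > 0)
}

relu_backward <- function(dY, cache) dY * cache$mask

# --- 2x2 max pool ----------------------------------------------------------

pool_indices <- function(H, W, N) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  h2 <- rep(seq_len(H2), W2)
  w2 <- rep(seq_len(W2), each = H2)
  base <- (2L * h2 - 1L) + H * (2L * w2 - 2L)
  img_off <- rep((0:(N - 1L)) * H * W, each = H2 * W2)
  list(
    i = list(rep(base, N) + img_off,
             rep(base + 1L, N) + img_off,
             rep(base + H, N) + img_off,
             rep(base + H + 1L, N) + img_off),
    H2 = H2, W2 = W2
  )
}

# Odd spatial dims are floor-cropped (last row/column ignored), the
# standard max-pool convention.
pool_forward <- function(X, H, W, N) {
  crop <- NULL
  if (H %% 2L != 0L || W %% 2L != 0L) {
    He <- H - H %% 2L; We <- W - W %% 2L
    if (He < 2L || We < 2L) {
      abort(sprintf("input too small to pool: %d x %d", H, W))
    }
    keep1 <- as.vector(outer(seq_len(He), (seq_len(We) - 1L) * H, "+"))
    keep <- as.vector(outer(keep1, (0:(N - 1L)) * H * W, "+"))
    crop <- list(keep = keep, H_full = H, W_full = W)
    X <- X[, keep, drop = FALSE]
    H <- He; W <- We
  }
  pi <- pool_indices(H, W, N)
  A <- X[, pi$i[[1]], drop = FALSE]; B <- X[, pi$i[[2]], drop = FALSE]
  Cc <- X[, pi$i[[3]], drop = FALSE]; D <- X[, pi$i[[4]], drop = FALSE]
  Y <- A; ch <- matrix(1L, nrow(Y), ncol(Y))
  upd <- B > Y; Y[upd] <- B[upd]; ch[upd] <- 2L
  upd <- Cc > Y; Y[upd] <- Cc[upd]; ch[upd] <- 3L
  upd <- D > Y; Y[upd] <- D[upd]; ch[upd] <- 4L
  list(Y = Y, choice = ch, idx = pi$i, H2 = pi$H2, W2 = pi$W2, crop = crop)
}

pool_backward <- function(dY, cache, C, H, W, N) {
  if (!is.null(cache$crop)) {
    He <- H - H %% 2L; We <- W - W %% 2L
    dXe <- matrix(0, C, He * We * N)
    for (g in 1:4) {
      dXe[, cache$idx[[g]]] <- dY * (cache$choice == g)
    }
    dX <- matrix(0, C, H * W * N)
    dX[, cache$crop$keep] <- dXe
    return(dX)
  }
  dX <- matrix(0, C, H * W * N)
  for (g in 1:4) {
    dX[, cache$idx[[g]]] <- dY * (cache$choice == g)
  }
  dX
}

# --- global average pool ---------------------------------------------------

gap_forward <- function(X, H, W, N) {
  hw <- H * W
  grp <- rep(seq_len(N), each = hw)
  Z <- t(rowsum(t(X), group = grp) / hw) # [C, N]
  Z
}

gap_backward <- function(dZ, H, W, N) {
  dZ[, rep(seq_len(N), each = H * W), drop = FALSE] / (H * W)
}

# --- softmax cross-entropy -------------------------------------------------

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# logits [N, K], y integer labels in 1..K
softmax_ce <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  p_true <- pmax(P[cbind(seq_len(n), y)], 1e-12)
  loss <- -mean(log(p_true))
  Yoh <- matrix(0, n, ncol(logits))
  Yoh[cbind(seq_len(n), y)] <- 1
  list(loss = loss, P = P, dlogits = (P - Yoh) / n)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) {
    lapply(p, function(x) x * 0)
  })
  list(m = zeros, v = zeros, t = 0L)
}

# params/grads: two-level named lists of numeric arrays with the same shape
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in names(params)) {
    for (j in names(params[[i]])) {
      g <- grads[[i]][[j]]
      if (is.null(g)) next
      state$m[[i]][[j]] <- beta1 * state$m[[i]][[j]] + (1 - beta1) * g
      state$v[[i]][[j]] <- beta2 * state$v[[i]][[j]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[j]] / bc1
      vhat <- state$v[[i]][[j]] / bc2
      params[[i]][[j]] <- params[[i]][[j]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
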