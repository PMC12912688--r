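# Minimal neural-network engine: just enough machinery for the benchmark's
# three tiny networks (the temporal-convolutional classifier, the gating
# network, and the two-layer meta-learner). Dense matrix algebra only; Adam
# optimizer; batch normalization with running statistics.

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Weighted binary cross-entropy (mean over batch); returns loss and dL/dlogit.
bce_weighted <- function(prob, y, pos_weight = 1) {
  eps <- 1e-12
  w <- ifelse(y == 1, pos_weight, 1)
  loss <- mean(w * (-y * log(pmax(prob, eps)) - (1 - y) * log(pmax(1 - prob, eps))))
  dlogit <- w * (prob - y) / length(y)
  list(loss = loss, dlogit = dlogit)
}

# ---- im2col for the 1-D convolution -----------------------------------
# R: pooled per-window feature rows (n x C). tvec: 1-based end-window index
# of each sample; a sample spans windows (t - T + 1) .. t. Returns the
# ((B*P) x (C*k)) patch matrix, rows grouped position-major (all samples at
# conv position 1, then position 2, ...). Column (c-1)*k + kk holds channel
# c at within-kernel offset kk.
im2col <- function(R, tvec, context, kernel) {
  B <- length(tvec)
  C <- ncol(R)
  P <- context - kernel + 1L
  M <- matrix(0, B * P, C * kernel)
  cols_base <- (seq_len(C) - 1L) * kernel
  for (p in seq_len(P)) {
    rows <- (p - 1L) * B + seq_len(B)
    for (kk in seq_len(kernel)) {
      M[rows, cols_base + kk] <- R[tvec - context + p + kk - 1L, , drop = FALSE]
    }
  }
  M
}

# ---- TCN core ---------------------------------------------------------

tcn_init_params <- function(spec, seed) {
  set.seed(seed)
  Ck <- spec$in_channels * spec$kernel_size
  F_ <- spec$conv_filters
  H <- spec$hidden_units
  list(
    Wc = matrix(stats::rnorm(Ck * F_, 0, sqrt(2 / Ck)), Ck, F_),
    bc = rep(0, F_),
    gamma = rep(1, F_),
    beta = rep(0, F_),
    W1 = matrix(stats::rnorm(F_ * H, 0, sqrt(2 / F_)), F_, H),
    b1 = rep(0, H),
    W2 = matrix(stats::rnorm(H, 0, sqrt(1 / H)), H, 1),
    b2 = 0
  )
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Forward pass. R = scaled feature rows, tvec = sample end indices.
# training = TRUE uses batch statistics (and returns a cache for backward);
# training = FALSE uses running statistics.
tcn_forward <- function(model, R, tvec, training = FALSE) {
  spec <- model$spec
  p_ <- model$params
  B <- length(tvec)
  P <- spec$context_windows - spec$kernel_size + 1L
  M <- im2col(R, tvec, spec$context_windows, spec$kernel_size)
  Z <- sweep(M %*% p_$Wc, 2, p_$bc, "+")
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(sweep(Z, 2, mu)^2)
  } else {
    mu <- model$run_mean
    v <- model$run_var
  }
  Zh <- sweep(sweep(Z, 2, mu), 2, sqrt(v + BN_EPS), "/")
  Y <- sweep(sweep(Zh, 2, p_$gamma, "*"), 2, p_$beta, "+")
  A <- pmax(Y, 0)
  if (P == 1L) {
    pool <- A
    amax <- NULL
  } else {
    pool <- A[seq_len(B), , drop = FALSE]
    amax <- matrix(1L, B, spec$conv_filters)
    for (p in 2:P) {
      blk <- A[(p - 1L) * B + seq_len(B), , drop = FALSE]
      upd <- blk > pool
      amax[upd] <- p
      pool[upd] <- blk[upd]
    }
  }
  H1pre <- sweep(pool %*% p_$W1, 2, p_$b1, "+")
  H1 <- pmax(H1pre, 0)
  logit <- drop(H1 %*% p_$W2) + p_$b2
  prob <- sigmoid(logit)
  out <- list(prob = prob, pool = pool)
  if (training) {
    out$cache <- list(M = M, Z = Z, Zh = Zh, Y = Y, A = A, mu = mu, v = v,
                      pool = pool, amax = amax, H1pre = H1pre, H1 = H1,
                      B = B, P = P)
  } else {
    out$cache <- list(pool = pool, H1pre = H1pre, H1 = H1, B = B)
  }
  out
}

# Backward pass through the whole network (training mode cache required).
tcn_backward <- function(model, cache, dlogit) {
  p_ <- model$params
  B <- cache$B
  P <- cache$P
  dlogit <- matrix(dlogit, ncol = 1)
  dW2 <- crossprod(cache$H1, dlogit)
  db2 <- sum(dlogit)
  dH1 <- dlogit %*% t(p_$W2)
  dH1pre <- dH1 * (cache$H1pre > 0)
  dW1 <- crossprod(cache$pool, dH1pre)
  db1 <- colSums(dH1pre)
  dpool <- dH1pre %*% t(p_$W1)
  if (P == 1L) {
    dA <- dpool
  } else {
    dA <- matrix(0, B * P, ncol(dpool))
    for (p in seq_len(P)) {
      mask <- cache$amax == p
      blk <- matrix(0, B, ncol(dpool))
      blk[mask] <- dpool[mask]
      dA[(p - 1L) * B + seq_len(B), ] <- blk
    }
  }
  dY <- dA * (cache$Y > 0)
  dgamma <- colSums(dY * cache$Zh)
  dbeta <- colSums(dY)
  dZh <- sweep(dY, 2, p_$gamma, "*")
  m <- nrow(dZh)
  inv_sd <- 1 / sqrt(cache$v + BN_EPS)
  mean_dZh <- colMeans(dZh)
  mean_dZhZh <- colMeans(dZh * cache$Zh)
  # batch-norm backward: dZ = (dZh - mean(dZh) - Zh * mean(dZh*Zh)) / sd
  dZ <- sweep(sweep(dZh, 2, mean_dZh) - sweep(cache$Zh, 2, mean_dZhZh, "*"),
              2, inv_sd, "*")
  dWc <- crossprod(cache$M, dZ)
  dbc <- colSums(dZ)
  list(Wc = dWc, bc = dbc, gamma = dgamma, beta = dbeta,
       W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# Dense head only (pool features fixed): forward + backward, used during
# personalization where the trunk is frozen.
head_forward <- function(params, pool) {
  H1pre <- sweep(pool %*% params$W1, 2, params$b1, "+")
  H1 <- pmax(H1pre, 0)
  logit <- drop(H1 %*% params$W2) + params$b2
  list(prob = sigmoid(logit), H1pre = H1pre, H1 = H1)
}

head_backward <- function(params, pool, fwd, dlogit) {
  dlogit <- matrix(dlogit, ncol = 1)
  dW2 <- crossprod(fwd$H1, dlogit)
  db2 <- sum(dlogit)
  dH1pre <- (dlogit %*% t(params$W2)) * (fwd$H1pre > 0)
  dW1 <- crossprod(pool, dH1pre)
  db1 <- colSums(dH1pre)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# ---- generic MLP (for GateNet and the two-layer meta-learner) ---------

mlp_init <- function(n_in, hidden, seed) {
  set.seed(seed)
  list(
    W1 = matrix(stats::rnorm(n_in * hidden, 0, sqrt(2 / n_in)), n_in, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1),
    b2 = 0
  )
}

mlp_forward <- function(params, X) {
  H1pre <- sweep(X %*% params$W1, 2, params$b1, "+")
  H1 <- pmax(H1pre, 0)
  logit <- drop(H1 %*% params$W2) + params$b2
  list(out = sigmoid(logit), logit = logit, H1pre = H1pre, H1 = H1)
}

mlp_backward <- function(params, X, fwd, dlogit) {
  dlogit <- matrix(dlogit, ncol = 1)
  dW2 <- crossprod(fwd$H1, dlogit)
  db2 <- sum(dlogit)
  dH1pre <- (dlogit %*% t(params$W2)) * (fwd$H1pre > 0)
  dW1 <- crossprod(X, dH1pre)
  db1 <- colSums(dH1pre)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}
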