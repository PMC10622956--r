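# Batched forward/backward primitives for the attention-augmented DeepNet.
#
# Layout convention (documented once, used everywhere):
#   * raw EEG batches are (channels, time, batch) arrays;
#   * after the temporal convolution, (filters, channels, time, batch);
#   * after the spatial convolution, (filters, time, batch);
#   * the classifier head emits (classes, batch) log-probabilities.
# All indexing is 1-based R; convolutions are "valid" along time unless
# stated otherwise. The three convolution kernels are compiled
# (src/conv_ops.cpp); attention, batchnorm, pooling, activations and the
# optimizers are plain R.

# ---- temporal convolution: shared 1-D filters applied per EEG channel ----

conv_time_fwd <- function(X, W) {
  d <- dim(X)                       # (C, T, B)
  .conv_time_fwd_cpp(X, W, d[1L], d[2L], d[3L])
}

conv_time_bwd <- function(dY, X, W) {
  d <- dim(X)
  .conv_time_bwd_cpp(dY, X, W, d[1L], d[2L], d[3L])
}

# ---- spatial convolution: collapses the EEG-channel axis ----

conv_spat_fwd <- function(X, W) {
  d <- dim(X)                       # (F, C, T1, B)
  .conv_spat_fwd_cpp(X, W, d[1L], d[2L], d[3L], d[4L])
}

conv_spat_bwd <- function(dY, X, W) {
  d <- dim(X)
  .conv_spat_bwd_cpp(dY, X, W, d[1L], d[2L], d[3L], d[4L])
}

# ---- ordinary 1-D block convolution over feature maps ----

conv1d_fwd <- function(X, W, k = 10L) {
  d <- dim(X)                       # (G, L, B)
  .conv1d_fwd_cpp(X, W, d[1L], d[2L], d[3L], k)
}

conv1d_bwd <- function(dY, X, W, k = 10L) {
  d <- dim(X)
  .conv1d_bwd_cpp(dY, X, W, d[1L], d[2L], d[3L], k)
}

# ---- batch normalization over feature maps ----

batchnorm_fwd <- function(X, gamma, beta, state, train, eps = 1e-5, momentum = 0.1) {
  d <- dim(X)
  Fm <- d[1L]
  n <- prod(d[-1L])
  Xm <- matrix(X, nrow = Fm)
  if (train) {
    mu <- rowMeans(Xm)
    v <- rowMeans(Xm * Xm) - mu * mu
    v <- pmax(v, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * v * n / max(n - 1, 1)
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (Xm - mu) * invstd
  out <- array(gamma * xhat + beta, d)
  list(out = out, cache = list(xhat = xhat, invstd = invstd, d = d), state = state)
}

batchnorm_bwd <- function(dY, gamma, cache) {
  d <- cache$d
  dY_mat <- matrix(dY, nrow = d[1L])
  xhat <- cache$xhat
  dgamma <- rowSums(dY_mat * xhat)
  dbeta <- rowSums(dY_mat)
  dxhat <- dY_mat * gamma
  dX <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- exponential linear unit ----

elu_fwd <- function(X) {
  out <- X
  neg <- X <= 0
  out[neg] <- exp(X[neg]) - 1
  out
}

elu_bwd <- function(dY, X, out) {
  g <- dY
  neg <- X <= 0
  g[neg] <- dY[neg] * (out[neg] + 1)
  g
}

# ---- max pooling, window 3 stride 3, along time ----

pool_fwd <- function(X) {
  d <- dim(X)
  L2 <- d[2L] %/% 3L
  s1 <- seq(1L, by = 3L, length.out = L2)
  X1 <- X[, s1, , drop = FALSE]
  X2 <- X[, s1 + 1L, , drop = FALSE]
  X3 <- X[, s1 + 2L, , drop = FALSE]
  Y <- pmax(X1, X2, X3)
  list(out = Y, cache = list(X1 = X1, X2 = X2, X3 = X3, s1 = s1, d = d))
}

pool_bwd <- function(dY, cache) {
  with(cache, {
    m1 <- X1 >= X2 & X1 >= X3
    m2 <- !m1 & X2 >= X3
    m3 <- !m1 & !m2
    dX <- array(0, d)
    dX[, s1, ] <- dY * m1
    dX[, s1 + 1L, ] <- dY * m2
    dX[, s1 + 2L, ] <- dY * m3
    dX
  })
}

# ---- attention modules on batches ----

# mean over the time axis of a (F, L, B) array -> (F, B)
.time_means <- function(X) {
  d <- dim(X)
  m <- colMeans(matrix(aperm(X, c(2L, 1L, 3L)), nrow = d[2L]))
  matrix(m, nrow = d[1L], ncol = d[3L])
}

.broadcast_fb <- function(w, L) {
  # (F, B) -> (F, L, B)
  d <- dim(w)
  aperm(array(w, c(d[1L], d[2L], L)), c(1L, 3L, 2L))
}

eca_fwd <- function(X, kern, bias) {
  d <- dim(X)
  k <- length(kern)
  p <- (k - 1L) / 2L
  y <- .time_means(X)                           # (F, B)
  ypad <- rbind(matrix(0, p, d[3L]), y, matrix(0, p, d[3L]))
  z <- matrix(bias, d[1L], d[3L])
  for (j in seq_len(k)) z <- z + kern[j] * ypad[j:(j + d[1L] - 1L), , drop = FALSE]
  w <- sigmoid(z)
  out <- X * .broadcast_fb(w, d[2L])
  list(out = out, cache = list(w = w, ypad = ypad, d = d))
}

eca_bwd <- function(dY, X, kern, cache) {
  d <- cache$d
  k <- length(kern)
  p <- (k - 1L) / 2L
  w <- cache$w
  ypad <- cache$ypad
  dw <- .time_means(dY * X) * d[2L]             # sum over time
  dz <- dw * w * (1 - w)
  dbias <- sum(dz)
  dkern <- numeric(k)
  for (j in seq_len(k)) {
    dkern[j] <- sum(dz * ypad[j:(j + d[1L] - 1L), , drop = FALSE])
  }
  dzpad <- rbind(matrix(0, p, d[3L]), dz, matrix(0, p, d[3L]))
  dy <- matrix(0, d[1L], d[3L])
  for (j in seq_len(k)) {
    dy <- dy + kern[k + 1L - j] * dzpad[j:(j + d[1L] - 1L), , drop = FALSE]
  }
  dX <- dY * .broadcast_fb(w, d[2L]) + .broadcast_fb(dy / d[2L], d[2L])
  list(dX = dX, dkern = dkern, dbias = dbias)
}

ca_fwd <- function(X, W, b) {
  d <- dim(X)
  y <- .time_means(X)                           # (C, B)
  z <- W %*% y + b
  w <- sigmoid(z)
  out <- X * .broadcast_fb(w, d[2L])
  list(out = out, cache = list(w = w, y = y, d = d))
}

ca_bwd <- function(dY, X, W, cache) {
  d <- cache$d
  w <- cache$w
  dw <- .time_means(dY * X) * d[2L]
  dz <- dw * w * (1 - w)
  dW <- dz %*% t(cache$y)
  db <- rowSums(dz)
  dy <- crossprod(W, dz)
  dX <- dY * .broadcast_fb(w, d[2L]) + .broadcast_fb(dy / d[2L], d[2L])
  list(dX = dX, dW = dW, db = db)
}

# ---- dropout (inverted) ----

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, cache = NULL))
  mask <- array((stats::runif(length(X)) >= p) / (1 - p), dim(X))
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- classifier head ----

classifier_fwd <- function(X, W, b) {
  d <- dim(X)                                   # (F, L, B)
  Xm <- matrix(X, nrow = d[1L] * d[2L])
  crossprod(W, Xm) + b                          # (K, B)
}

classifier_bwd <- function(dY, X, W) {
  d <- dim(X)
  Xm <- matrix(X, nrow = d[1L] * d[2L])
  dW <- Xm %*% t(dY)
  db <- rowSums(dY)
  dX <- array(W %*% dY, d)
  list(dX = dX, dW = dW, db = db)
}

log_softmax <- function(Z) {
  m <- apply(Z, 2L, max)
  Zs <- sweep(Z, 2L, m)
  sweep(Zs, 2L, log(colSums(exp(Zs))))
}
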