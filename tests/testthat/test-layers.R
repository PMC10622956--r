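# The batched layer engine: compiled convolution kernels against naive
# loop oracles, and the full backward pass against numerical gradients.

ns <- asNamespace("ecaselect")

test_that("compiled temporal convolution matches a naive loop", {
  set.seed(21)
  C <- 3; T <- 20; B <- 2; F <- 4; k <- 10
  X <- array(rnorm(C * T * B), c(C, T, B))
  W <- matrix(rnorm(F * k), F, k)
  out <- ns$conv_time_fwd(X, W)
  T1 <- T - k + 1
  expect_identical(dim(out), as.integer(c(F, C, T1, B)))
  for (b in 1:B) for (cc in 1:C) for (t in 1:T1) for (f in 1:F) {
    expect_equal(out[f, cc, t, b], sum(W[f, ] * X[cc, t:(t + k - 1), b]),
                 tolerance = 1e-12)
  }
})

test_that("compiled spatial convolution matches a naive loop", {
  set.seed(22)
  F <- 3; C <- 4; T1 <- 6; B <- 2; Fo <- 5
  A <- array(rnorm(F * C * T1 * B), c(F, C, T1, B))
  W <- matrix(rnorm(F * C * Fo), F * C, Fo)
  out <- ns$conv_spat_fwd(A, W)
  expect_identical(dim(out), as.integer(c(Fo, T1, B)))
  for (b in 1:B) for (t in 1:T1) for (fo in 1:Fo) {
    ref <- sum(W[, fo] * as.vector(A[, , t, b]))
    expect_equal(out[fo, t, b], ref, tolerance = 1e-12)
  }
})

test_that("compiled block convolution matches a naive loop", {
  set.seed(23)
  G <- 3; L <- 25; B <- 2; F <- 4; k <- 10
  X <- array(rnorm(G * L * B), c(G, L, B))
  W <- matrix(rnorm(G * k * F), G * k, F)
  out <- ns$conv1d_fwd(X, W)
  T1 <- L - k + 1
  expect_identical(dim(out), as.integer(c(F, T1, B)))
  for (b in 1:B) for (t in 1:T1) for (f in 1:F) {
    ref <- sum(matrix(W[, f], G, k) * X[, t:(t + k - 1), b])
    expect_equal(out[f, t, b], ref, tolerance = 1e-12)
  }
})

test_that("max pooling matches apply() and routes gradients to the argmax", {
  set.seed(24)
  X <- array(rnorm(4 * 11 * 3), c(4, 11, 3))
  r <- ns$pool_fwd(X)
  L2 <- 3
  ref <- array(NA_real_, c(4, L2, 3))
  for (f in 1:4) for (t in 1:L2) for (b in 1:3) {
    ref[f, t, b] <- max(X[f, (3 * t - 2):(3 * t), b])
  }
  expect_equal(r$out, ref)
  dY <- array(1, dim(ref))
  dX <- ns$pool_bwd(dY, r$cache)
  # each pooled window receives exactly one unit of gradient
  expect_equal(sum(dX), length(ref))
  for (f in 1:4) for (t in 1:L2) for (b in 1:3) {
    win <- dX[f, (3 * t - 2):(3 * t), b]
    expect_equal(sum(win), 1)
    expect_equal(X[f, (3 * t - 2):(3 * t), b][win == 1], ref[f, t, b])
  }
  # the trailing remainder columns get no gradient
  expect_true(all(dX[, 10:11, ] == 0))
})

test_that("batchnorm standardizes each feature map in training mode", {
  set.seed(25)
  X <- array(rnorm(5 * 30 * 4, mean = 3, sd = 2), c(5, 30, 4))
  state <- list(running_mean = numeric(5), running_var = rep(1, 5))
  r <- ns$batchnorm_fwd(X, gamma = rep(1, 5), beta = numeric(5),
                        state = state, train = TRUE)
  m <- matrix(r$out, 5)
  expect_equal(rowMeans(m), numeric(5), tolerance = 1e-8)
  expect_equal(apply(m, 1, function(z) mean(z^2)), rep(1, 5),
               tolerance = 1e-4)
})

test_that("log-softmax output exponentiates to a probability simplex", {
  set.seed(26)
  Z <- matrix(rnorm(4 * 7, sd = 10), 4, 7)
  lp <- ns$log_softmax(Z)
  expect_equal(colSums(exp(lp)), rep(1, 7), tolerance = 1e-6)
  expect_true(all(lp < 0))
})

test_that("backpropagation matches numerical gradients through the full stack", {
  set.seed(27)
  C <- 3; T <- 1000; K <- 2; B <- 2
  hp <- hyperparameters(dropout_rate = 0)
  spec <- build_eca_deepnet(C, T, K, hp)
  init <- ns$init_params(spec)
  par <- init$par; state <- init$state
  X <- array(rnorm(C * T * B), c(C, T, B))
  y <- c(1L, 2L)
  loss_fn <- function(p) {
    lp <- ns$net_forward(spec, p, state, X, train = TRUE)$logp
    -mean(lp[cbind(y, seq_len(B))])
  }
  fw <- ns$net_forward(spec, par, state, X, train = TRUE)
  lp <- fw$logp
  dZ <- exp(lp); dZ[cbind(y, 1:B)] <- dZ[cbind(y, 1:B)] - 1; dZ <- dZ / B
  grads <- ns$net_backward(spec, par, fw$caches, dZ)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (el in names(grads[[nm]])) {
      g <- grads[[nm]][[el]]
      for (i in sample(length(g), min(3, length(g)))) {
        p2 <- par; p2[[nm]][[el]][i] <- p2[[nm]][[el]][i] + eps
        p1 <- par; p1[[nm]][[el]][i] <- p1[[nm]][[el]][i] - eps
        num <- (loss_fn(p2) - loss_fn(p1)) / (2 * eps)
        rel <- abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i]))
        expect_lt(rel, 1e-3, label = paste("gradient mismatch", nm, el, i))
      }
    }
  }
})
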