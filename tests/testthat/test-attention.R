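# Attention primitives: adaptive kernel size, pooling, the two attention
# forms and recalibration.

# independent oracle: brute-force nearest-odd search, ties resolved upward
nearest_odd_up <- function(x) {
  cand <- seq(1, max(9, 2 * ceiling(x) + 3), by = 2)
  d <- abs(cand - x)
  cand[max(which(d == min(d)))]
}

test_that("adaptive kernel size matches the nearest-odd rule", {
  expect_identical(adaptive_kernel_size(32), 3L)
  expect_identical(adaptive_kernel_size(256), 5L)
  expect_identical(adaptive_kernel_size(2), 1L)
  for (C in c(1:10, 2^(5:12), 100, 1000)) {
    expect_identical(adaptive_kernel_size(C),
                     as.integer(nearest_odd_up(log2(C) / 2 + 1 / 2)),
                     info = paste("C =", C))
  }
})

test_that("adaptive kernel size is odd and non-decreasing over 1..4096", {
  k <- vapply(1:4096, adaptive_kernel_size, integer(1))
  expect_true(all(k %% 2L == 1L))
  expect_true(all(diff(k) >= 0L))
  expect_true(all(k >= 1L))
})

test_that("adaptive kernel size rejects non-positive channel counts", {
  expect_error(adaptive_kernel_size(0), "positive")
  expect_error(adaptive_kernel_size(-3), "positive")
})

test_that("global average pooling equals the brute-force mean", {
  x <- array(7, c(5, 10, 3))
  expect_equal(global_average_pool(x), rep(7, 5))
  x2 <- matrix(0, 4, 4)
  x2[2, ] <- c(1, 2, 3, 5)
  expect_equal(global_average_pool(x2)[2], 2.75)
  expect_equal(global_average_pool(array(0, c(3, 4))), rep(0, 3))

  set.seed(11)
  for (i in 1:5) {
    d <- c(sample(2:6, 1), sample(2:9, 1), sample(1:4, 1))
    x <- array(rnorm(prod(d)), d)
    loop <- vapply(seq_len(d[1]), function(cc) {
      s <- 0; n <- 0
      for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        s <- s + x[cc, j, k]; n <- n + 1
      }
      s / n
    }, numeric(1))
    expect_lt(max(abs(global_average_pool(x) - loop)), 1e-10)
  }
})

test_that("ECA attention applies a same-length padded convolution and sigmoid", {
  p0 <- eca_params(8, k = 3)
  expect_equal(eca_attention(rnorm(8), p0), rep(0.5, 8))

  p <- eca_params(3, k = 3, kernel = c(0, 1, 0))
  w <- eca_attention(c(0, 2, 0), p)
  expect_equal(w, c(0.5, 1 / (1 + exp(-2)), 0.5), tolerance = 1e-12)

  p32 <- eca_params(32)
  expect_length(eca_attention(rnorm(32), p32), 32)

  # hand convolution oracle with explicit zero padding
  set.seed(3)
  y <- rnorm(6)
  kern <- rnorm(5)
  pp <- eca_params(6, k = 5, kernel = kern, bias = 0.3)
  ypad <- c(0, 0, y, 0, 0)
  zref <- vapply(1:6, function(i) sum(kern * ypad[i:(i + 4)]), numeric(1))
  expect_equal(eca_attention(y, pp), 1 / (1 + exp(-(zref + 0.3))),
               tolerance = 1e-12)
})

test_that("a one-hot center kernel reduces ECA attention to sigmoid(y + bias)", {
  set.seed(5)
  for (C in c(4, 9, 17)) {
    y <- rnorm(C)
    p <- eca_params(C, k = 3, kernel = c(0, 1, 0), bias = -0.2)
    expect_equal(eca_attention(y, p), 1 / (1 + exp(-(y - 0.2))),
                 tolerance = 1e-12)
  }
})

test_that("over-long ECA kernels are rejected", {
  expect_error(eca_params(2, k = 5), "twice")
  p <- eca_params(8, k = 7)
  expect_error(eca_attention(rnorm(3), p), "twice")
})

test_that("CA attention is a full linear map through a sigmoid", {
  p0 <- ca_params(5)
  expect_equal(ca_attention(rnorm(5), p0), rep(0.5, 5))

  p <- ca_params(2, weight_matrix = 10 * diag(2))
  w <- ca_attention(c(1, -1), p)
  expect_equal(w, c(1 / (1 + exp(-10)), 1 / (1 + exp(10))), tolerance = 1e-9)

  expect_error(ca_attention(rnorm(3), p0), "does not match")
})

test_that("attention parameter counts follow their closed forms", {
  expect_identical(n_attention_params(ca_params(22)), 506L)
  for (C in c(2, 5, 22, 64)) {
    p <- ca_params(C)
    # direct enumeration of trainable scalars
    expect_identical(n_attention_params(p),
                     length(p$weight_matrix) + length(p$bias))
    expect_identical(n_attention_params(p), as.integer(C^2 + C))
  }
  for (C in c(4, 32, 64, 128, 256)) {
    p <- eca_params(C)
    expect_identical(n_attention_params(p),
                     length(p$kernel) + length(p$bias))
  }
})

test_that("attention weights always lie strictly inside (0, 1)", {
  set.seed(9)
  for (i in 1:20) {
    C <- sample(2:40, 1)
    y <- rnorm(C)
    k <- adaptive_kernel_size(C)
    w1 <- eca_attention(y, eca_params(C, k = k, kernel = rnorm(k),
                                      bias = rnorm(1)))
    # weight scale ~ 1/sqrt(C): the magnitude a trained layer would carry
    w2 <- ca_attention(y, ca_params(C, matrix(rnorm(C * C, sd = 1 / sqrt(C)),
                                              C, C), rnorm(C)))
    expect_true(all(w1 > 0 & w1 < 1))
    expect_true(all(w2 > 0 & w2 < 1))
  }
})

test_that("recalibration scales channels and preserves shape", {
  x <- array(rnorm(24), c(2, 3, 4))
  expect_equal(recalibrate(x, c(1, 1)), x)
  expect_equal(recalibrate(x, c(0, 0)), x * 0)
  xc <- array(2, c(3, 5))
  expect_equal(recalibrate(xc, c(0.5, 1, 1))[1, ], rep(1, 5))

  set.seed(13)
  for (i in 1:10) {
    d <- c(sample(1:6, 1), sample(1:8, 1), sample(1:3, 1))
    x <- array(rnorm(prod(d)), d)
    w <- runif(d[1])
    y <- recalibrate(x, w)
    expect_identical(dim(y), dim(x))
    for (cc in seq_len(d[1])) {
      expect_equal(y[cc, , ], w[cc] * x[cc, , ], tolerance = 1e-12)
    }
  }
  expect_error(recalibrate(x, c(1, 2)), "does not match")
})
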