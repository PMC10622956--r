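# Architecture spec: shape tracing, parameter bookkeeping, forward sanity.

ns <- asNamespace("ecaselect")

test_that("declared parameter counts equal a direct enumeration of scalars", {
  for (C in c(8, 22)) {
    spec <- build_eca_deepnet(C, 1000, 4)
    set.seed(1)
    par <- ns$init_params(spec)$par
    for (nm in names(par)) {
      expect_identical(count_parameters(spec, nm),
                       as.integer(sum(lengths(par[[nm]]))),
                       info = paste(C, nm))
    }
    expect_identical(count_parameters(spec, "total"),
                     as.integer(sum(unlist(lapply(par, lengths)))))
    # the CA layer accounts for exactly C^2 + C of the total
    expect_identical(count_parameters(spec, "CA-Layer"), as.integer(C^2 + C))
    expect_identical(count_parameters(spec, "total") -
                       count_parameters(spec, "CA-Layer"),
                     as.integer(sum(spec$parameters, na.rm = TRUE) - C^2 - C))
  }
})

test_that("declared layer shapes equal the shapes the engine produces", {
  C <- 5; T <- 1000; B <- 2
  spec <- build_eca_deepnet(C, T, 4, hyperparameters(dropout_rate = 0))
  set.seed(2)
  init <- ns$init_params(spec)
  X <- array(rnorm(C * T * B), c(C, T, B))
  cur <- X
  for (i in seq_len(nrow(spec))) {
    kind <- spec$kind[i]
    nm <- spec$layer[i]
    p <- init$par[[nm]]
    cur <- switch(
      kind,
      input = cur,
      ca = ns$ca_fwd(cur, p$W, p$b)$out,
      conv_time = ns$conv_time_fwd(cur, p$W),
      conv_spat = ns$conv_spat_fwd(cur, p$W),
      conv1d = ns$conv1d_fwd(cur, p$W),
      batchnorm = ns$batchnorm_fwd(cur, p$gamma, p$beta, init$state[[nm]],
                                   train = TRUE)$out,
      elu = ns$elu_fwd(cur),
      pool = ns$pool_fwd(cur)$out,
      eca = ns$eca_fwd(cur, p$kernel, p$bias)$out,
      dropout = cur,
      classifier = ns$classifier_fwd(cur, p$W, p$b),
      logsoftmax = ns$log_softmax(cur)
    )
    declared <- spec$output[[i]]
    got <- dim(cur)
    # declared shapes are batch-free (maps, time, spatial); the engine
    # appends the batch axis and stores the temporal-conv stage as
    # (maps, channels, time, batch)
    engine_view <- switch(
      kind,
      input = declared,
      conv_time = got[c(1, 3, 2)],
      classifier = c(got[1], 1L, 1L),
      logsoftmax = got[1],
      got[-length(got)]
    )
    n_cmp <- min(length(engine_view), length(declared))
    expect_identical(as.integer(engine_view)[seq_len(n_cmp)],
                     declared[seq_len(n_cmp)], info = nm)
    if (length(declared) > n_cmp) {
      expect_true(all(declared[-seq_len(n_cmp)] == 1L), info = nm)
    }
  }
})

test_that("too-short inputs fail with the offending layer named", {
  expect_error(build_eca_deepnet(22, 300, 4), "Conv-[0-9]")
  expect_error(build_eca_deepnet(22, 120, 4), "Conv|Pool")
  expect_error(build_eca_deepnet(1, 1000, 4), "channels")
})

test_that("temporal arithmetic is conv L-9 then pool floor(L/3)", {
  # brute-force trace vs the spec's declared time lengths
  L <- 1000L
  lens <- integer(0)
  for (blk in 1:4) {
    if (blk > 1) L <- L - 9L
    lens <- c(lens, if (blk > 1) L else (L <- L - 9L))
    L <- L %/% 3L
    lens <- c(lens, L)
  }
  expect_identical(lens, c(991L, 330L, 321L, 107L, 98L, 32L, 23L, 7L))
})

test_that("forward pass on zero input is finite and normalized", {
  C <- 4; T <- 1000
  spec <- build_eca_deepnet(C, T, 4, hyperparameters(dropout_rate = 0.5))
  set.seed(3)
  init <- ns$init_params(spec)
  X <- array(0, c(C, T, 3))
  out <- ns$net_forward(spec, init$par, init$state, X, train = FALSE,
                        keep = FALSE)$logp
  expect_true(all(is.finite(out)))
  expect_equal(colSums(exp(out)), rep(1, 3), tolerance = 1e-6)
})

test_that("elu follows its closed form", {
  expect_identical(elu(0), exp(0) - 1)
  expect_identical(elu(2), 2)
  expect_equal(elu(-1), exp(-1) - 1, tolerance = 1e-12)
  x <- seq(-3, 3, by = 0.25)
  expect_equal(elu(x), ifelse(x > 0, x, exp(x) - 1), tolerance = 1e-12)
})

test_that("hyperparameters reject out-of-range values", {
  expect_error(hyperparameters(dropout_rate = 0.95), "0.9")
  expect_error(hyperparameters(learning_rate = 1), "1e-1")
  expect_error(hyperparameters(batch_size = 10), "batch_size")
  expect_error(hyperparameters(weight_decay = 0.5), "weight_decay")
  expect_error(hyperparameters(optimizer = "SGD"), "arg")
  hp <- hyperparameters()
  expect_s3_class(hp, "eca_hyperparameters")
  expect_identical(hp$seed, 20200220L)
})

test_that("subject presets round-trip into valid hyperparameters", {
  for (s in c(1, 5, 9)) {
    for (ph in c("before", "after")) {
      hp <- preset_hyperparameters(s, ph, epochs = 10)
      expect_s3_class(hp, "eca_hyperparameters")
    }
  }
  expect_error(preset_hyperparameters(12), "unknown subject")
})
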