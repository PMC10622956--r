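#' Training hyperparameters
#'
#' Validated container for the hyperparameters searched over when tuning
#' the network: dropout rate in `[0, 0.9]`, optimizer one of AdamW,
#' Adadelta or Adagrad, learning rate in `[1e-5, 1e-1]`, batch size in
#' `{4, 8, 16, 32, 64}` and weight decay in `{1e-5, 1e-4, 1e-3, 1e-2}`.
#' Defaults are the modal values of the per-subject tuning results shipped
#' in [subject_presets]. `seed` fixes every source of randomness in
#' [train_model()] (initialization, shuffling, dropout, validation split).
#'
#' @param dropout_rate Dropout probability after blocks 1-3.
#' @param optimizer One of `"AdamW"`, `"Adadelta"`, `"Adagrad"`.
#' @param learning_rate Step size.
#' @param batch_size Mini-batch size.
#' @param weight_decay Decoupled weight decay (AdamW) or L2 penalty.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation loss (epochs);
#'   `Inf` disables early stopping.
#' @param validation_split Fraction of trials held out for validation
#'   during training (0 disables).
#' @param seed Integer random seed.
#' @return A list of class `eca_hyperparameters`.
#' @export
hyperparameters <- function(dropout_rate = 0.5, optimizer = "AdamW",
                            learning_rate = 1e-3, batch_size = 16,
                            weight_decay = 1e-4, epochs = 200,
                            patience = 30, validation_split = 0.2,
                            seed = 20200220) {
  if (dropout_rate < 0 || dropout_rate > 0.9) {
    stop("`dropout_rate` must lie in [0, 0.9]", call. = FALSE)
  }
  optimizer <- match.arg(optimizer, c("AdamW", "Adadelta", "Adagrad"))
  if (learning_rate < 1e-5 || learning_rate > 1e-1) {
    stop("`learning_rate` must lie in [1e-5, 1e-1]", call. = FALSE)
  }
  if (!batch_size %in% c(4, 8, 16, 32, 64)) {
    stop("`batch_size` must be one of 4, 8, 16, 32, 64", call. = FALSE)
  }
  if (!weight_decay %in% c(1e-5, 1e-4, 1e-3, 1e-2)) {
    stop("`weight_decay` must be one of 1e-5, 1e-4, 1e-3, 1e-2", call. = FALSE)
  }
  if (epochs < 1) stop("`epochs` must be positive", call. = FALSE)
  if (validation_split < 0 || validation_split >= 1) {
    stop("`validation_split` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(dropout_rate = dropout_rate, optimizer = optimizer,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         weight_decay = weight_decay, epochs = as.integer(epochs),
         patience = patience, validation_split = validation_split,
         seed = as.integer(seed)),
    class = "eca_hyperparameters"
  )
}

# ---- optimizers over a nested parameter list ----

.map2_params <- function(p, g, f) {
  for (nm in names(g)) {
    for (el in names(g[[nm]])) {
      p[[nm]][[el]] <- f(p[[nm]][[el]], g[[nm]][[el]], nm, el)
    }
  }
  p
}

make_optimizer <- function(hp) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  lr <- hp$learning_rate
  wd <- hp$weight_decay
  slot <- function(tab, nm, el, proto) {
    if (is.null(st[[tab]])) st[[tab]] <- list()
    key <- paste0(nm, "$", el)
    if (is.null(st[[tab]][[key]])) st[[tab]][[key]] <- proto * 0
    key
  }
  if (hp$optimizer == "AdamW") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    function(par, grads) {
      st$t <- st$t + 1L
      .map2_params(par, grads, function(p, g, nm, el) {
        key <- slot("m", nm, el, p); slot("v", nm, el, p)
        st$m[[key]] <- b1 * st$m[[key]] + (1 - b1) * g
        st$v[[key]] <- b2 * st$v[[key]] + (1 - b2) * g * g
        mhat <- st$m[[key]] / (1 - b1^st$t)
        vhat <- st$v[[key]] / (1 - b2^st$t)
        p - lr * mhat / (sqrt(vhat) + eps) - lr * wd * p
      })
    }
  } else if (hp$optimizer == "Adagrad") {
    eps <- 1e-10
    function(par, grads) {
      .map2_params(par, grads, function(p, g, nm, el) {
        g <- g + wd * p
        key <- slot("a", nm, el, p)
        st$a[[key]] <- st$a[[key]] + g * g
        p - lr * g / (sqrt(st$a[[key]]) + eps)
      })
    }
  } else {
    rho <- 0.9; eps <- 1e-6
    function(par, grads) {
      .map2_params(par, grads, function(p, g, nm, el) {
        g <- g + wd * p
        ka <- slot("a", nm, el, p); kd <- slot("d", nm, el, p)
        st$a[[ka]] <- rho * st$a[[ka]] + (1 - rho) * g * g
        dx <- -sqrt(st$d[[kd]] + eps) / sqrt(st$a[[ka]] + eps) * g
        st$d[[kd]] <- rho * st$d[[kd]] + (1 - rho) * dx * dx
        p + lr * dx
      })
    }
  }
}

#' Train the attention-augmented DeepNet on a sample set
#'
#' Fits the network with mini-batch gradient descent under the
#' negative-log-likelihood loss matching the log-softmax head. A fraction
#' of *trials* (not crops, so sibling crops never straddle the split) is
#' held out for validation; early stopping restores the parameters of the
#' best validation epoch. Fully deterministic given `hp$seed`.
#'
#' @param samples A [sample_set()].
#' @param hp [hyperparameters()].
#' @param spec Optional pre-built [build_eca_deepnet()] spec; defaults to
#'   the architecture sized for `samples`.
#' @param verbose Print per-epoch progress.
#' @return An object of class `eca_deepnet`: the spec, fitted parameters,
#'   batchnorm state, per-epoch `history` tibble, `hp`, `seed` and the
#'   channel names trained on.
#' @export
train_model <- function(samples, hp = hyperparameters(), spec = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(samples, "sample_set"))
  y <- as.integer(samples$labels)
  if (length(unique(y)) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  d <- dim(samples$x)                     # (C, T, N)
  if (is.null(spec)) {
    spec <- build_eca_deepnet(d[1L], d[2L], nlevels(samples$labels), hp)
  }
  if (attr(spec, "channels") != d[1L] || attr(spec, "time_samples") != d[2L]) {
    stop("sample shape does not match network spec", call. = FALSE)
  }

  set.seed(hp$seed)
  init <- init_params(spec)
  par <- init$par
  state <- init$state
  opt <- make_optimizer(hp)

  n <- d[3L]
  # trial-wise validation split
  val_idx <- integer(0)
  if (hp$validation_split > 0) {
    trials <- unique(samples$trial_ids)
    n_val <- max(1L, round(hp$validation_split * length(trials)))
    val_trials <- sample(trials, n_val)
    val_idx <- which(samples$trial_ids %in% val_trials)
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  best <- list(loss = Inf, par = par, state = state, epoch = 0L)
  hist <- vector("list", hp$epochs)
  wait <- 0L

  for (ep in seq_len(hp$epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; ep_hits <- 0L
    for (start in seq(1L, length(ord), by = hp$batch_size)) {
      bi <- ord[start:min(start + hp$batch_size - 1L, length(ord))]
      X <- samples$x[, , bi, drop = FALSE]
      yy <- y[bi]
      B <- length(bi)
      fw <- net_forward(spec, par, state, X, train = TRUE)
      state <- fw$state
      lp <- fw$logp
      pick <- cbind(yy, seq_len(B))      # (row = class, col = sample) pairs
      loss <- -mean(lp[pick])
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
      }
      ep_loss <- ep_loss + loss * B
      ep_hits <- ep_hits + sum(max.col(t(lp)) == yy)
      # d(loss)/d(logits): (softmax - onehot)/B
      dZ <- exp(lp)
      dZ[pick] <- dZ[pick] - 1
      dZ <- dZ / B
      grads <- net_backward(spec, par, fw$caches, dZ)
      par <- opt(par, grads)
    }
    train_loss <- ep_loss / length(ord)
    train_acc <- ep_hits / length(ord)
    val_loss <- NA_real_; val_acc <- NA_real_
    if (length(val_idx)) {
      ev <- .net_eval(spec, par, state, samples$x[, , val_idx, drop = FALSE],
                      y[val_idx])
      val_loss <- ev$loss; val_acc <- ev$acc
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = train_loss,
                                 train_acc = train_acc, val_loss = val_loss,
                                 val_acc = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val %.4f/%.3f",
                      ep, train_loss, train_acc, val_loss, val_acc))
    }
    monitor <- if (length(val_idx)) val_loss else train_loss
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, par = par, state = state, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }

  structure(
    list(spec = spec, par = best$par, state = best$state,
         history = dplyr::bind_rows(hist), hp = hp, seed = hp$seed,
         best_epoch = best$epoch, channel_names = samples$channel_names),
    class = "eca_deepnet"
  )
}

# evaluation helper: loss + accuracy in eval mode, batched for memory
.net_eval <- function(spec, par, state, X, y, chunk = 32L) {
  n <- dim(X)[3L]
  loss <- 0; hits <- 0L
  for (start in seq(1L, n, by = chunk)) {
    bi <- start:min(start + chunk - 1L, n)
    lp <- net_forward(spec, par, state, X[, , bi, drop = FALSE],
                      train = FALSE, keep = FALSE)$logp
    pick <- cbind(y[bi], seq_along(bi))
    loss <- loss + sum(-lp[pick])
    hits <- hits + sum(max.col(t(lp)) == y[bi])
  }
  list(loss = loss / n, acc = hits / n)
}

#' Predict class log-probabilities or labels
#'
#' @param object A fitted `eca_deepnet`.
#' @param samples A [sample_set()] with matching channels and window length.
#' @param type `"class"` for factor labels, `"logprob"` for the
#'   classes-by-samples matrix of log-probabilities.
#' @param ... Unused.
#' @return Factor of predicted labels, or a matrix of log-probabilities.
#' @export
predict.eca_deepnet <- function(object, samples, type = c("class", "logprob"),
                                ...) {
  type <- match.arg(type)
  stopifnot(inherits(samples, "sample_set"))
  d <- dim(samples$x)
  if (attr(object$spec, "channels") != d[1L] ||
      attr(object$spec, "time_samples") != d[2L]) {
    stop("sample shape does not match the fitted network", call. = FALSE)
  }
  n <- d[3L]
  K <- attr(object$spec, "classes")
  lp <- matrix(NA_real_, K, n)
  for (start in seq(1L, n, by = 32L)) {
    bi <- start:min(start + 31L, n)
    lp[, bi] <- net_forward(object$spec, object$par, object$state,
                            samples$x[, , bi, drop = FALSE],
                            train = FALSE, keep = FALSE)$logp
  }
  if (type == "logprob") return(lp)
  factor(levels(samples$labels)[max.col(t(lp))], levels = levels(samples$labels))
}

#' Classification accuracy of a fitted model
#'
#' Fraction of correctly classified crops; with `vote = "trial"`, crops
#' are first aggregated into a per-trial majority vote (summed
#' log-probabilities) and accuracy is computed over trials.
#'
#' @param model A fitted `eca_deepnet`.
#' @param samples A [sample_set()].
#' @param vote `"crop"` (default) or `"trial"`.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate <- function(model, samples, vote = c("crop", "trial")) {
  vote <- match.arg(vote)
  if (dim(samples$x)[3L] == 0L) stop("empty sample set", call. = FALSE)
  lp <- predict(model, samples, type = "logprob")
  y <- as.integer(samples$labels)
  if (vote == "crop") {
    return(mean(max.col(t(lp)) == y))
  }
  trials <- unique(samples$trial_ids)
  hits <- vapply(trials, function(tr) {
    i <- samples$trial_ids == tr
    pred <- which.max(rowSums(lp[, i, drop = FALSE]))
    pred == y[i][1L]
  }, logical(1L))
  mean(hits)
}
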