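#' The attention-augmented DeepNet architecture
#'
#' Builds the declarative layer stack of the network used for embedded EEG
#' channel selection: a channel-attention (CA) layer over the raw
#' electrodes, a temporal convolution (32 filters, kernel 10) followed by a
#' spatial convolution across electrodes (kernel 1 x channels), then four
#' convolution--batchnorm--ELU--maxpool blocks with filter counts
#' (32, 64, 128, 256), an efficient-channel-attention (ECA) module after
#' every pooling stage, dropout after the first three blocks, and a
#' convolutional classifier head with a log-softmax output. Every row of
#' the returned tibble carries the symbolically traced output shape and the
#' trainable parameter count of that layer.
#'
#' Convolutions inside the four blocks carry no bias terms; the classifier
#' convolution does. Each ECA module's kernel size is set from its feature
#' dimension by [adaptive_kernel_size()] and it carries a single bias, so
#' its parameter count is `k + 1`; the CA layer holds a full `C x C` matrix
#' plus a per-channel bias (`C^2 + C` parameters). The classifier kernel
#' spans the whole temporal extent remaining after block 4 (7 samples for
#' the default 22 x 1000 input).
#'
#' @param channels Number of EEG electrodes (>= 2).
#' @param time_samples Samples per training window (>= 100; the four
#'   stacked convolution/pooling stages require at least 927).
#' @param classes Number of target classes.
#' @param hp Hyperparameters, see [hyperparameters()]; only the dropout
#'   rate enters the spec.
#' @return A tibble of class `eca_deepnet_spec` with columns `block`,
#'   `layer`, `kind`, `filters`, `kernel`, `output` (list of integer
#'   shapes), `output_label`, `activation` and `parameters`, plus
#'   attributes `channels`, `time_samples` and `classes`.
#' @examples
#' spec <- build_eca_deepnet(22, 1000, 4)
#' count_parameters(spec, "Conv-Spat")
#' count_parameters(spec, "total")
#' @export
build_eca_deepnet <- function(channels, time_samples, classes = 4,
                              hp = hyperparameters()) {
  if (channels < 2) stop("`channels` must be at least 2", call. = FALSE)
  if (time_samples < 100) stop("`time_samples` must be at least 100", call. = FALSE)
  filters <- c(32L, 64L, 128L, 256L)
  conv_k <- 10L
  pool_k <- 3L

  rows <- list()
  add <- function(block, layer, kind, filters = NA_integer_, kernel = "",
                  output, activation = "", parameters = NA_integer_, ...) {
    rows[[length(rows) + 1L]] <<- c(
      list(block = block, layer = layer, kind = kind, filters = filters,
           kernel = kernel, output = list(as.integer(output)),
           activation = activation, parameters = parameters),
      list(...)
    )
  }

  C <- as.integer(channels)
  K <- as.integer(classes)
  L <- as.integer(time_samples)

  add(NA_integer_, "Input", "input", output = c(C, L))
  add(NA_integer_, "CA-Layer", "ca", output = c(C, L),
      parameters = C * C + C)
  add(1L, "Conv-Time", "conv_time", filters = filters[1L],
      kernel = sprintf("%d × 1", conv_k),
      output = c(filters[1L], L - conv_k + 1L, C), activation = "Linear",
      parameters = filters[1L] * conv_k)
  t_len <- L - conv_k + 1L
  if (t_len < 1L) {
    stop("`time_samples` too short for layer Conv-Time", call. = FALSE)
  }
  add(1L, "Conv-Spat", "conv_spat", filters = filters[1L],
      kernel = sprintf("1 × %d", C),
      output = c(filters[1L], t_len, 1L), activation = "Linear",
      parameters = filters[1L] * filters[1L] * C)

  f_in <- filters[1L]
  for (blk in seq_len(4L)) {
    f <- filters[blk]
    if (blk > 1L) {
      new_len <- t_len - conv_k + 1L
      if (new_len < 1L) {
        stop("`time_samples` too short for layer Conv-", blk, call. = FALSE)
      }
      add(blk, paste0("Conv-", blk), "conv1d", filters = f,
          kernel = sprintf("%d × 1", conv_k),
          output = c(f, new_len, 1L), activation = "Linear",
          parameters = f * f_in * conv_k)
      t_len <- new_len
    }
    add(blk, paste0("BatchNorm-", blk), "batchnorm",
        output = c(f, t_len, 1L), parameters = 2L * f)
    add(blk, paste0("Activation-", blk), "elu", output = c(f, t_len, 1L),
        activation = "ELU")
    t_len <- t_len %/% pool_k
    if (t_len < 1L) {
      stop("`time_samples` too short for layer Pool-", blk, call. = FALSE)
    }
    add(blk, paste0("Pool-", blk), "pool",
        kernel = sprintf("%d × 1", pool_k), output = c(f, t_len, 1L))
    k_eca <- adaptive_kernel_size(f)
    add(blk, paste0("ECA-", blk), "eca", output = c(f, t_len, 1L),
        parameters = k_eca + 1L)
    if (blk < 4L) {
      add(blk, paste0("Dropout-", blk), "dropout", output = c(f, t_len, 1L))
    }
    f_in <- f
  }

  cls_k <- t_len
  add(4L, "Conv-Classifier", "classifier", filters = K,
      kernel = sprintf("%d × 1", cls_k), output = c(K, 1L, 1L),
      activation = "Linear", parameters = K * f_in * cls_k + K)
  add(4L, "Activation-Classifier", "logsoftmax", output = c(K),
      activation = "Logsoftmax")

  spec <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  spec$output_label <- vapply(
    spec$output, function(o) paste(o, collapse = " × "), character(1L)
  )
  spec <- spec[, c("block", "layer", "kind", "filters", "kernel", "output",
                   "output_label", "activation", "parameters")]
  attr(spec, "channels") <- C
  attr(spec, "time_samples") <- L
  attr(spec, "classes") <- K
  attr(spec, "dropout_rate") <- hp$dropout_rate
  class(spec) <- c("eca_deepnet_spec", class(spec))
  spec
}

#' Count trainable parameters of a network spec
#'
#' @param spec An `eca_deepnet_spec` from [build_eca_deepnet()].
#' @param layer A layer name as printed in the spec (e.g. `"Conv-Spat"`,
#'   `"ECA-3"`), or `"total"` for the sum over all layers.
#' @return Non-negative integer count of trainable scalars.
#' @export
count_parameters <- function(spec, layer = "total") {
  stopifnot(inherits(spec, "eca_deepnet_spec"))
  if (identical(layer, "total")) {
    return(sum(spec$parameters, na.rm = TRUE))
  }
  i <- match(layer, spec$layer)
  if (is.na(i)) stop("unknown layer: ", layer, call. = FALSE)
  p <- spec$parameters[i]
  if (is.na(p)) 0L else p
}

#' Exponential linear unit
#'
#' `elu(x)` is `x` for positive `x` and `exp(x) - 1` otherwise; the
#' activation used throughout the network.
#'
#' @param x Numeric vector or array.
#' @return Same shape as `x`.
#' @export
elu <- function(x) {
  out <- x
  neg <- x <= 0
  out[neg] <- exp(x[neg]) - 1
  out
}

# Glorot-uniform draw for a parameter with given fan-in/out
.glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Initialize trainable parameters and batchnorm state for a spec.
# Consumes the R RNG stream; callers seed it.
init_params <- function(spec) {
  C <- attr(spec, "channels")
  par <- list()
  state <- list()
  conv_k <- 10L
  for (i in seq_len(nrow(spec))) {
    kind <- spec$kind[i]
    nm <- spec$layer[i]
    if (kind == "ca") {
      par[[nm]] <- list(W = .glorot(c(C, C), C, C), b = numeric(C))
    } else if (kind == "conv_time") {
      f <- spec$filters[i]
      par[[nm]] <- list(W = .glorot(c(f, conv_k), conv_k, f * conv_k))
    } else if (kind == "conv_spat") {
      f <- spec$filters[i]
      fan_in <- f * C
      par[[nm]] <- list(W = .glorot(c(fan_in, f), fan_in, f))
    } else if (kind == "conv1d") {
      f <- spec$filters[i]
      f_in <- spec$output[[i - 1L]][1L]
      par[[nm]] <- list(W = .glorot(c(f_in * conv_k, f), f_in * conv_k, f * conv_k))
    } else if (kind == "batchnorm") {
      f <- spec$output[[i]][1L]
      par[[nm]] <- list(gamma = rep(1, f), beta = numeric(f))
      state[[nm]] <- list(running_mean = numeric(f), running_var = rep(1, f))
    } else if (kind == "eca") {
      f <- spec$output[[i]][1L]
      k <- spec$parameters[i] - 1L
      par[[nm]] <- list(kernel = as.numeric(.glorot(k, k, k)), bias = 0)
    } else if (kind == "classifier") {
      K <- spec$filters[i]
      prev <- spec$output[[i - 1L]]
      fan_in <- prev[1L] * prev[2L]
      par[[nm]] <- list(W = .glorot(c(fan_in, K), fan_in, K), b = numeric(K))
    }
  }
  list(par = par, state = state)
}

# Full forward pass. X: (C, T, B). Returns log-probabilities and, when
# `keep = TRUE`, per-layer caches for backprop.
net_forward <- function(spec, par, state, X, train = FALSE, keep = train) {
  caches <- if (keep) vector("list", nrow(spec)) else NULL
  drop_p <- attr(spec, "dropout_rate")
  cur <- X
  for (i in seq_len(nrow(spec))) {
    kind <- spec$kind[i]
    nm <- spec$layer[i]
    if (kind == "input") {
      next
    } else if (kind == "ca") {
      r <- ca_fwd(cur, par[[nm]]$W, par[[nm]]$b)
      if (keep) caches[[i]] <- list(x = cur, c = r$cache)
      cur <- r$out
    } else if (kind == "conv_time") {
      if (keep) caches[[i]] <- list(x = cur)
      cur <- conv_time_fwd(cur, par[[nm]]$W)
    } else if (kind == "conv_spat") {
      if (keep) caches[[i]] <- list(x = cur)
      cur <- conv_spat_fwd(cur, par[[nm]]$W)
    } else if (kind == "conv1d") {
      if (keep) caches[[i]] <- list(x = cur)
      cur <- conv1d_fwd(cur, par[[nm]]$W)
    } else if (kind == "batchnorm") {
      r <- batchnorm_fwd(cur, par[[nm]]$gamma, par[[nm]]$beta,
                         state[[nm]], train)
      state[[nm]] <- r$state
      if (keep) caches[[i]] <- r$cache
      cur <- r$out
    } else if (kind == "elu") {
      out <- elu_fwd(cur)
      if (keep) caches[[i]] <- list(x = cur, out = out)
      cur <- out
    } else if (kind == "pool") {
      r <- pool_fwd(cur)
      if (keep) caches[[i]] <- r$cache
      cur <- r$out
    } else if (kind == "eca") {
      r <- eca_fwd(cur, par[[nm]]$kernel, par[[nm]]$bias)
      if (keep) caches[[i]] <- list(x = cur, c = r$cache)
      cur <- r$out
    } else if (kind == "dropout") {
      r <- dropout_fwd(cur, drop_p, train)
      if (keep) caches[[i]] <- r$cache
      cur <- r$out
    } else if (kind == "classifier") {
      if (keep) caches[[i]] <- list(x = cur)
      cur <- classifier_fwd(cur, par[[nm]]$W, par[[nm]]$b)
    } else if (kind == "logsoftmax") {
      cur <- log_softmax(cur)
    }
  }
  list(logp = cur, caches = caches, state = state)
}

# Backward pass from d(loss)/d(logits pre log-softmax). Returns gradient
# list parallel to `par`.
net_backward <- function(spec, par, caches, dZ) {
  grads <- list()
  cur <- dZ
  for (i in rev(seq_len(nrow(spec)))) {
    kind <- spec$kind[i]
    nm <- spec$layer[i]
    if (kind %in% c("input", "logsoftmax")) next
    cc <- caches[[i]]
    if (kind == "classifier") {
      r <- classifier_bwd(cur, cc$x, par[[nm]]$W)
      grads[[nm]] <- list(W = r$dW, b = r$db)
      cur <- r$dX
    } else if (kind == "dropout") {
      cur <- dropout_bwd(cur, cc)
    } else if (kind == "eca") {
      r <- eca_bwd(cur, cc$x, par[[nm]]$kernel, cc$c)
      grads[[nm]] <- list(kernel = r$dkern, bias = r$dbias)
      cur <- r$dX
    } else if (kind == "pool") {
      cur <- pool_bwd(cur, cc)
    } else if (kind == "elu") {
      cur <- elu_bwd(cur, cc$x, cc$out)
    } else if (kind == "batchnorm") {
      r <- batchnorm_bwd(cur, par[[nm]]$gamma, cc)
      grads[[nm]] <- list(gamma = r$dgamma, beta = r$dbeta)
      cur <- r$dX
    } else if (kind == "conv1d") {
      r <- conv1d_bwd(cur, cc$x, par[[nm]]$W)
      grads[[nm]] <- list(W = r$dW)
      cur <- r$dX
    } else if (kind == "conv_spat") {
      r <- conv_spat_bwd(cur, cc$x, par[[nm]]$W)
      grads[[nm]] <- list(W = r$dW)
      cur <- r$dX
    } else if (kind == "conv_time") {
      r <- conv_time_bwd(cur, cc$x, par[[nm]]$W)
      grads[[nm]] <- list(W = r$dW)
      cur <- r$dX
    } else if (kind == "ca") {
      r <- ca_bwd(cur, cc$x, par[[nm]]$W, cc$c)
      grads[[nm]] <- list(W = r$dW, b = r$db)
      cur <- r$dX
    }
  }
  grads
}

#' @export
print.eca_deepnet_spec <- function(x, ...) {
  cat("Attention-augmented DeepNet spec: ", attr(x, "channels"),
      " channels × ", attr(x, "time_samples"), " samples → ",
      attr(x, "classes"), " classes\n", sep = "")
  df <- data.frame(block = x$block, layer = x$layer, filters = x$filters,
                   kernel = x$kernel, output = x$output_label,
                   activation = x$activation, parameters = x$parameters)
  print(df, row.names = FALSE, na.print = "")
  cat("Total trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}
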