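#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Adaptive kernel size for efficient channel attention
#'
#' Maps a channel dimension `C` to the kernel size of the shared 1-D
#' convolution used by an ECA module: the odd integer nearest to
#' `log2(C)/2 + 1/2`. When that value falls exactly between two odd
#' integers (it is an even integer), the larger odd kernel is taken, so
#' that higher channel dimensions always get at least as much cross-channel
#' context. The mapping is non-decreasing in `C` and always at least 1.
#'
#' @param n_channels Positive integer; the channel dimension of the feature
#'   block the ECA module attends over.
#' @return An odd positive integer kernel size.
#' @examples
#' adaptive_kernel_size(32)  # 3
#' adaptive_kernel_size(128) # 5
#' @export
adaptive_kernel_size <- function(n_channels) {
  if (length(n_channels) != 1L || !is.finite(n_channels) || n_channels < 1 ||
      n_channels != floor(n_channels)) {
    stop("`n_channels` must be a single positive integer", call. = FALSE)
  }
  x <- log2(n_channels) / 2 + 1 / 2
  k <- floor(x)
  if (k %% 2 == 0) k <- k + 1
  max(1L, as.integer(k))
}

#' Channel-wise global average pooling
#'
#' Reduces a feature block to one statistic per channel: the mean of each
#' channel's plane. Channels are the *first* dimension of `x` everywhere in
#' this package; the remaining dimensions (time, and width when present)
#' are averaged out.
#'
#' @param x A matrix (`channels x time`) or array whose first dimension
#'   indexes channels; all entries must be finite.
#' @return A numeric vector with one mean per channel.
#' @export
global_average_pool <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = length(x), ncol = 1L)
  d <- dim(x)
  if (prod(d[-1]) < 1L) stop("channel planes are empty", call. = FALSE)
  m <- rowMeans(matrix(x, nrow = d[1L]))
  if (!all(is.finite(m))) stop("non-finite values in feature block", call. = FALSE)
  m
}

#' Parameters of an ECA attention module
#'
#' Container for the shared 1-D convolution of an efficient-channel-attention
#' module: `k` kernel taps plus a single bias, `k` chosen by
#' [adaptive_kernel_size()] unless given. Trainable parameter count is
#' therefore `k + 1`.
#'
#' @param n_channels Channel dimension the module attends over.
#' @param k Odd kernel size; defaults to `adaptive_kernel_size(n_channels)`.
#' @param kernel,bias Optional initial values (zeros by default).
#' @return An object of class `eca_params` with elements `kernel`, `bias`,
#'   `k` and `n_channels`.
#' @export
eca_params <- function(n_channels, k = adaptive_kernel_size(n_channels),
                       kernel = numeric(k), bias = 0) {
  if (k %% 2 == 0 || k < 1) stop("`k` must be an odd positive integer", call. = FALSE)
  if (k > 2 * n_channels) {
    stop("kernel size ", k, " exceeds twice the channel dimension ", n_channels,
         call. = FALSE)
  }
  if (length(kernel) != k) stop("`kernel` must have length `k`", call. = FALSE)
  structure(
    list(kernel = as.numeric(kernel), bias = as.numeric(bias)[1L],
         k = as.integer(k), n_channels = as.integer(n_channels)),
    class = "eca_params"
  )
}

#' Parameters of the channel-attention (CA) layer
#'
#' The input-facing attention layer replaces the shared small convolution
#' with a full `C x C` linear map plus a per-channel bias, so it can couple
#' *any* pair of EEG electrodes (including homologous sites on opposite
#' hemispheres), not just neighbours in channel order. Trainable parameter
#' count is `C^2 + C`.
#'
#' @param n_channels EEG channel count `C`.
#' @param weight_matrix Optional `C x C` matrix (zeros by default).
#' @param bias Optional length-`C` bias vector (zeros by default).
#' @return An object of class `ca_params`.
#' @export
ca_params <- function(n_channels,
                      weight_matrix = matrix(0, n_channels, n_channels),
                      bias = numeric(n_channels)) {
  weight_matrix <- as.matrix(weight_matrix)
  if (!all(dim(weight_matrix) == n_channels)) {
    stop("`weight_matrix` must be ", n_channels, " x ", n_channels, call. = FALSE)
  }
  if (length(bias) != n_channels) {
    stop("`bias` must have length ", n_channels, call. = FALSE)
  }
  structure(
    list(weight_matrix = weight_matrix, bias = as.numeric(bias),
         n_channels = as.integer(n_channels)),
    class = "ca_params"
  )
}

#' Count trainable parameters of an attention module
#'
#' @param params An [eca_params()] or [ca_params()] object.
#' @return Integer number of trainable scalars (`k + 1` for ECA,
#'   `C^2 + C` for the CA layer).
#' @export
n_attention_params <- function(params) {
  if (inherits(params, "eca_params")) return(params$k + 1L)
  if (inherits(params, "ca_params")) {
    C <- params$n_channels
    return(C * C + C)
  }
  stop("`params` must be `eca_params` or `ca_params`", call. = FALSE)
}

#' ECA attention weights from a pooled descriptor
#'
#' Applies the shared 1-D convolution of an ECA module to the pooled
#' channel descriptor and squashes through a sigmoid:
#' `w = sigmoid(conv1d_k(y) + bias)`. The convolution is length-preserving
#' ("same"): the descriptor is zero-padded by `(k-1)/2` on each side.
#'
#' @param y Numeric vector, one pooled statistic per channel.
#' @param params An [eca_params()] object.
#' @return Attention weights in `(0, 1)`, same length as `y`.
#' @export
eca_attention <- function(y, params) {
  stopifnot(inherits(params, "eca_params"))
  k <- params$k
  C <- length(y)
  if (k > 2 * C) {
    stop("kernel size ", k, " exceeds twice the descriptor length ", C,
         call. = FALSE)
  }
  p <- (k - 1L) / 2L
  ypad <- c(numeric(p), y, numeric(p))
  z <- numeric(C)
  for (j in seq_len(k)) z <- z + params$kernel[j] * ypad[j:(j + C - 1L)]
  sigmoid(z + params$bias)
}

#' CA-layer attention weights from a pooled descriptor
#'
#' The fully connected form of channel attention:
#' `w = sigmoid(W %*% y + b)`. No dimensionality reduction takes place;
#' the output has one weight per channel.
#'
#' @param y Numeric vector, one pooled statistic per channel.
#' @param params A [ca_params()] object whose matrix side equals `length(y)`.
#' @return Attention weights in `(0, 1)`, same length as `y`.
#' @export
ca_attention <- function(y, params) {
  stopifnot(inherits(params, "ca_params"))
  if (params$n_channels != length(y)) {
    stop("descriptor length ", length(y), " does not match CA layer size ",
         params$n_channels, call. = FALSE)
  }
  as.numeric(sigmoid(params$weight_matrix %*% y + params$bias))
}

#' Recalibrate a feature block by attention weights
#'
#' Scales every channel of `x` by its attention weight, leaving the shape
#' untouched: channel `c` of the output is `w[c]` times channel `c` of the
#' input.
#'
#' @param x A matrix or array whose first dimension indexes channels.
#' @param w Numeric weight vector, one entry per channel.
#' @return An object with exactly the shape of `x`.
#' @export
recalibrate <- function(x, w) {
  d <- if (is.null(dim(x))) c(length(x), 1L) else dim(x)
  if (length(w) != d[1L]) {
    stop("length of `w` (", length(w), ") does not match channel count (",
         d[1L], ")", call. = FALSE)
  }
  out <- x * as.numeric(w)  # column-major: channels vary fastest, so w recycles per channel
  out
}
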