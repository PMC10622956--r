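#' Extract per-electrode attention weights from a fitted model
#'
#' The CA layer's attention is input-dependent (it is a function of each
#' sample's pooled channel descriptor), so the channel weight used for
#' ranking is the *expected* attention: the per-sample CA attention
#' vectors computed over all provided samples, averaged elementwise. As an
#' alternative summary, `method = "weight_norm"` ranks channels by the L2
#' norm of each channel's row of the CA weight matrix (squashed to `(0,1)`
#' by `r / (1 + r)` to preserve the attention-vector range contract);
#' the averaged attention is the default.
#'
#' @param model A fitted `eca_deepnet` from [train_model()].
#' @param samples A [sample_set()] with the channel count the model was
#'   trained on (normally its training set).
#' @param method `"attention"` (default) or `"weight_norm"`.
#' @return Named numeric vector of length `C`, entries in `(0, 1)`.
#' @export
extract_channel_weights <- function(model, samples,
                                    method = c("attention", "weight_norm")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "eca_deepnet"), inherits(samples, "sample_set"))
  C <- attr(model$spec, "channels")
  if (dim(samples$x)[1L] != C) {
    stop("sample channel count does not match the model's CA layer",
         call. = FALSE)
  }
  pars <- model$par[["CA-Layer"]]
  if (method == "weight_norm") {
    r <- sqrt(rowSums(pars$W^2))
    w <- r / (1 + r)
  } else {
    y <- .time_means(samples$x)                  # (C, N) pooled descriptors
    w <- rowMeans(sigmoid(pars$W %*% y + pars$b))
  }
  stats::setNames(as.numeric(w), samples$channel_names)
}

#' Rank channels by attention weight
#'
#' Sorts channels by descending weight; ties keep the original channel
#' order (lower index first).
#'
#' @param w Numeric weight vector (one entry per channel).
#' @param channel_names Channel names, same length as `w`; defaults to
#'   `names(w)`.
#' @return A tibble of class `channel_ranking` with columns `rank`,
#'   `channel` and `weight`, one row per channel.
#' @export
rank_channels <- function(w, channel_names = names(w)) {
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_along(w))
  }
  if (length(w) != length(channel_names)) {
    stop("`w` and `channel_names` must have the same length", call. = FALSE)
  }
  ord <- order(-w, seq_along(w))
  out <- tibble::tibble(rank = seq_along(w),
                        channel = as.character(channel_names)[ord],
                        weight = as.numeric(w)[ord])
  class(out) <- c("channel_ranking", class(out))
  out
}

#' Take the top of a channel ranking
#'
#' The optimal subset of size `n_c` is simply the first `n_c` entries of
#' the importance ranking, in ranking order.
#'
#' @param ranking A [rank_channels()] tibble.
#' @param n_c Subset size, `1 <= n_c <= C`.
#' @return A tibble of class `channel_subset` (the ranking prefix) with
#'   attribute `n_c`.
#' @export
select_subset <- function(ranking, n_c) {
  stopifnot(inherits(ranking, "channel_ranking"))
  if (n_c < 1 || n_c > nrow(ranking)) {
    stop("`n_c` must lie in 1..", nrow(ranking), call. = FALSE)
  }
  out <- ranking[seq_len(n_c), ]
  attr(out, "n_c") <- as.integer(n_c)
  class(out) <- c("channel_subset", setdiff(class(out), "channel_subset"))
  out
}

#' Restrict a sample set to a channel subset
#'
#' Drops all channels outside the subset and reorders the remaining rows
#' to subset (ranking) order; labels and trial provenance are untouched.
#'
#' @param samples A [sample_set()].
#' @param subset A [select_subset()] result, a `channel_ranking`, or a
#'   character vector of channel names.
#' @return A reduced [sample_set()].
#' @export
restrict_to_subset <- function(samples, subset) {
  stopifnot(inherits(samples, "sample_set"))
  chans <- if (is.character(subset)) subset else subset$channel
  idx <- match(chans, samples$channel_names)
  if (anyNA(idx)) {
    stop("unknown channel(s): ", paste(chans[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  sample_set(samples$x[idx, , , drop = FALSE], samples$labels,
             samples$trial_ids, chans, samples$sampling_rate)
}

#' Accuracy/latency sweep over channel-subset sizes
#'
#' Runs the full selection loop: train on all channels, extract and rank
#' the attention weights, then for every requested subset size take the
#' ranking prefix, *rebuild* the network for that channel count (spatial
#' convolution kernel `1 x n_c`, CA layer `n_c^2 + n_c` parameters),
#' retrain from scratch with the same seed, and score on the held-out
#' samples. Prediction time is the wall-clock time of scoring the held-out
#' set and is hardware-dependent.
#'
#' @param samples Training [sample_set()].
#' @param holdout Held-out [sample_set()] used for accuracy (its crops are
#'   never trained on).
#' @param hp [hyperparameters()] applied to every (re)training.
#' @param sizes Integer vector of subset sizes.
#' @param vote Accuracy aggregation, see [evaluate()].
#' @param verbose Print progress.
#' @return A tibble of class `channel_sweep` with one row per size:
#'   `n_c`, `accuracy`, `prediction_time_s` and a `channels` list-column,
#'   plus attributes `ranking` and `full_model`.
#' @export
channel_sweep <- function(samples, holdout, hp = hyperparameters(),
                          sizes = c(8, 22), vote = "crop", verbose = FALSE) {
  C <- dim(samples$x)[1L]
  if (any(sizes < 1 | sizes > C)) {
    stop("`sizes` must lie within 1..", C, call. = FALSE)
  }
  full <- train_model(samples, hp)
  w <- extract_channel_weights(full, samples)
  ranking <- rank_channels(w)
  rows <- lapply(sizes, function(nc) {
    sub <- select_subset(ranking, nc)
    if (nc == C) {
      # selecting every channel is a no-op: reuse the full-channel model so
      # the sweep row reproduces the direct train/evaluate result exactly
      model <- full
      tr <- holdout
    } else {
      model <- train_model(restrict_to_subset(samples, sub), hp)
      tr <- restrict_to_subset(holdout, sub)
    }
    t0 <- proc.time()[["elapsed"]]
    acc <- evaluate(model, tr, vote = vote)
    dt <- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("n_c = %2d: accuracy %.3f", nc, acc))
    tibble::tibble(n_c = as.integer(nc), accuracy = acc,
                   prediction_time_s = dt, channels = list(sub$channel))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "ranking") <- ranking
  attr(out, "full_model") <- NULL   # kept out of the result to stay light
  class(out) <- c("channel_sweep", class(out))
  out
}

#' Fractional channel reduction
#'
#' Relative reduction of the electrode count when an `n_c`-channel subset
#' replaces the full montage, as a percentage: selecting 8 of 22 channels
#' is a 63.64% reduction.
#'
#' @param n_c Subset size.
#' @param n_channels Full montage size.
#' @return Percentage in `[0, 100)`.
#' @export
channel_reduction_pct <- function(n_c, n_channels) {
  if (n_c < 1 || n_c > n_channels) stop("`n_c` must lie in 1..n_channels",
                                        call. = FALSE)
  100 * (1 - n_c / n_channels)
}
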