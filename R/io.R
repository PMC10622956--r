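# File interfaces: rankings and accuracy tables as CSV, subsets and reports
# as JSON/plain text, model checkpoints and sample sets as single-file RDS
# archives.

#' Write / read a channel ranking as CSV
#'
#' Columns `rank`, `channel_name`, `mean_weight`.
#'
#' @param ranking A [rank_channels()] tibble.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `channel_ranking` tibble (reader).
#' @export
write_ranking_csv <- function(ranking, path) {
  stopifnot(inherits(ranking, "channel_ranking"))
  utils::write.csv(
    data.frame(rank = ranking$rank, channel_name = ranking$channel,
               mean_weight = ranking$weight),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_ranking_csv
#' @export
read_ranking_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(rank = as.integer(df$rank),
                        channel = as.character(df$channel_name),
                        weight = as.numeric(df$mean_weight))
  class(out) <- c("channel_ranking", class(out))
  out
}

#' Write a channel ranking as JSON
#'
#' Includes the per-channel dispersion (standard deviation of the
#' per-sample attention vectors) when supplied.
#'
#' @param ranking A [rank_channels()] tibble.
#' @param path Output file.
#' @param dispersion Optional named numeric vector of per-channel weight
#'   standard deviations.
#' @return `path`, invisibly.
#' @export
write_ranking_json <- function(ranking, path, dispersion = NULL) {
  stopifnot(inherits(ranking, "channel_ranking"))
  obj <- list(ranking = data.frame(rank = ranking$rank,
                                   channel_name = ranking$channel,
                                   mean_weight = ranking$weight))
  if (!is.null(dispersion)) {
    obj$ranking$weight_sd <- as.numeric(dispersion[ranking$channel])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a channel subset
#'
#' `write_subset()` writes one channel name per line;
#' `write_subset_json()` adds the subset size and provenance (seed and a
#' checksum of the originating model's parameters).
#'
#' @param subset A [select_subset()] result or character vector.
#' @param path Output file.
#' @param seed,model Optional provenance for the JSON variant.
#' @return `path`, invisibly.
#' @export
write_subset <- function(subset, path) {
  chans <- if (is.character(subset)) subset else subset$channel
  writeLines(chans, path)
  invisible(path)
}

#' @rdname write_subset
#' @export
write_subset_json <- function(subset, path, seed = NULL, model = NULL) {
  chans <- if (is.character(subset)) subset else subset$channel
  obj <- list(n_c = length(chans), channels = chans)
  if (!is.null(seed)) obj$seed <- seed
  if (!is.null(model)) obj$model_checksum <- model_checksum(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subset
#' @export
read_subset <- function(path) readLines(path)

#' Checksum of a fitted model's parameters
#'
#' Order-stable digest (sum and L2 norm of all trainable scalars, printed
#' to 10 significant digits) used to tag selection outputs with the model
#' that produced them.
#'
#' @param model A fitted `eca_deepnet`.
#' @return A character scalar.
#' @export
model_checksum <- function(model) {
  v <- unlist(model$par, use.names = FALSE)
  sprintf("n%d-s%.10g-q%.10g", length(v), sum(v), sqrt(sum(v^2)))
}

#' Write training history as CSV
#'
#' Columns `epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`.
#'
#' @param model A fitted `eca_deepnet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(model, path) {
  utils::write.csv(as.data.frame(model$history), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' A single-file archive holding the fitted parameter state, the
#' architecture spec, batchnorm state, hyperparameters and seed.
#'
#' @param model A fitted `eca_deepnet`.
#' @param path Checkpoint file.
#' @return `path` invisibly (save); the restored `eca_deepnet` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "eca_deepnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "eca_deepnet")) stop("not a model checkpoint", call. = FALSE)
  model
}

#' Save / load a sample set
#'
#' Single-file archive of the sample array, labels, trial provenance and
#' channel names.
#'
#' @param samples A [sample_set()].
#' @param path File path.
#' @return `path` invisibly (save); a [sample_set()] (load).
#' @export
save_sampleset <- function(samples, path) {
  stopifnot(inherits(samples, "sample_set"))
  saveRDS(samples, path)
  invisible(path)
}

#' @rdname save_sampleset
#' @export
load_sampleset <- function(path) {
  s <- readRDS(path)
  if (!inherits(s, "sample_set")) stop("not a sample-set archive", call. = FALSE)
  s
}
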