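#' Per-subject tuned hyperparameter presets
#'
#' Hyperparameters found by a per-subject TPE search on the four-class,
#' 22-channel motor-imagery benchmark, before (full 22-channel montage) and
#' after (8-channel subset) channel selection. Shipped as optional starting
#' points; [hyperparameters()] defaults to the modal values of the
#' `"before"` column set.
#'
#' @format A tibble with one row per subject and selection phase:
#' \describe{
#'   \item{subject}{Subject number, 1-9.}
#'   \item{phase}{`"before"` or `"after"` channel selection.}
#'   \item{dropout_rate, optimizer, learning_rate, batch_size, weight_decay}{
#'     Tuned values, see [hyperparameters()].}
#' }
#' @export
subject_presets <- local({
  before <- data.frame(
    subject = 1:9, phase = "before",
    dropout_rate = c(0.5, 0.3, 0.5, 0.4, 0.4, 0.4, 0.7, 0.3, 0.4),
    optimizer = c("AdamW", "AdamW", "Adagrad", "AdamW", "AdamW", "AdamW",
                  "Adagrad", "Adagrad", "AdamW"),
    learning_rate = c(1.049e-3, 1.922e-4, 9.036e-3, 2.940e-4, 5.330e-5,
                      2.639e-4, 1.181e-2, 2.276e-2, 5.243e-4),
    batch_size = c(32L, 4L, 8L, 16L, 4L, 4L, 16L, 16L, 16L),
    weight_decay = c(1e-5, 1e-3, 1e-4, 1e-4, 1e-4, 1e-4, 1e-2, 1e-5, 1e-2)
  )
  after <- data.frame(
    subject = 1:9, phase = "after",
    dropout_rate = c(0.2, 0.5, 0.6, 0.3, 0.2, 0.4, 0.3, 0.5, 0.2),
    optimizer = "AdamW",
    learning_rate = c(8.234e-5, 2.852e-3, 2.362e-2, 2.159e-4, 6.413e-4,
                      6.915e-4, 3.533e-4, 1.058e-3, 2.092e-3),
    batch_size = c(16L, 16L, 4L, 8L, 16L, 16L, 8L, 4L, 16L),
    weight_decay = c(1e-2, 1e-3, 1e-2, 1e-2, 1e-4, 1e-4, 1e-5, 1e-2, 1e-2)
  )
  tibble::as_tibble(rbind(before, after))
})

#' Hyperparameters from a subject preset
#'
#' @param subject Subject number (1-9).
#' @param phase `"before"` (full montage) or `"after"` (post-selection).
#' @param ... Overrides passed on to [hyperparameters()] (e.g. `epochs`).
#' @return An `eca_hyperparameters` object.
#' @export
preset_hyperparameters <- function(subject, phase = c("before", "after"), ...) {
  phase <- match.arg(phase)
  row <- subject_presets[subject_presets$subject == subject &
                           subject_presets$phase == phase, ]
  if (nrow(row) != 1L) stop("unknown subject: ", subject, call. = FALSE)
  args <- utils::modifyList(
    list(dropout_rate = row$dropout_rate, optimizer = row$optimizer,
         learning_rate = row$learning_rate, batch_size = row$batch_size,
         weight_decay = row$weight_decay),
    list(...)
  )
  do.call(hyperparameters, args)
}
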