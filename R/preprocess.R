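#' Continuous multichannel EEG recording
#'
#' @param signal Channels-by-samples numeric matrix (microvolts).
#' @param channel_names Character vector, one name per signal row.
#' @param sampling_rate Sampling rate in Hz.
#' @param events Tibble/data frame with columns `sample` (1-based index of
#'   the cue onset) and `label` (class of the trial).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, channel_names, sampling_rate, events) {
  signal <- as.matrix(signal)
  if (nrow(signal) != length(channel_names)) {
    stop("`channel_names` must have one entry per signal row", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  events <- tibble::as_tibble(events)
  stopifnot(all(c("sample", "label") %in% names(events)))
  if (nrow(events) && (min(events$sample) < 1 ||
                       max(events$sample) > ncol(signal))) {
    stop("event sample indices fall outside the recording", call. = FALSE)
  }
  structure(
    list(signal = signal, channel_names = as.character(channel_names),
         sampling_rate = sampling_rate, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording: ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples @ ", x$sampling_rate, " Hz, ", nrow(x$events), " events\n",
      sep = "")
  invisible(x)
}

#' Set of cropped training samples
#'
#' Samples are stored as a `(channels, time, n)` array — channels first,
#' matching the layout used by the network — with one label and one source
#' trial id per sample.
#'
#' @param x Numeric array of dim `(channels, time, n)`.
#' @param labels Factor (or coercible) of length `n`.
#' @param trial_ids Integer vector of length `n` mapping each crop to its
#'   source trial.
#' @param channel_names Character vector of length `channels`.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(x, labels, trial_ids, channel_names,
                       sampling_rate = 250) {
  d <- dim(x)
  if (length(d) != 3L) stop("`x` must be a (channels, time, n) array", call. = FALSE)
  labels <- as.factor(labels)
  if (length(labels) != d[3L] || length(trial_ids) != d[3L]) {
    stop("`labels` and `trial_ids` must have one entry per sample", call. = FALSE)
  }
  if (length(channel_names) != d[1L]) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  structure(
    list(x = x, labels = labels, trial_ids = as.integer(trial_ids),
         channel_names = as.character(channel_names),
         sampling_rate = sampling_rate),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  d <- dim(x$x)
  cat("Sample set: ", d[3L], " samples x ", d[1L], " channels x ", d[2L],
      " time points; classes: ",
      paste(sprintf("%s (%d)", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.sample_set <- function(x) dim(x$x)

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`, so zero phase shift) independently to every
#' channel. Shape, channel names and events are unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Band edges; must satisfy
#'   `0 < low_hz < high_hz < sampling_rate / 2`.
#' @param order Butterworth order (default 4).
#' @return A filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low_hz = 1, high_hz = 40, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < sampling_rate/2",
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$signal <- t(apply(rec$signal, 1L, function(ch)
    signal::filtfilt(bf, ch)))
  dimnames(out$signal) <- dimnames(rec$signal)
  out
}

#' Exponential-moving-average standardization
#'
#' Normalizes each channel against causally tracked running statistics:
#' `m_t = decay * m_{t-1} + (1 - decay) * x_t`, a running variance of the
#' residual maintained the same way, and output
#' `(x_t - m_t) / max(sqrt(v_t), eps)`. The running mean starts at the
#' first sample and the running variance at 1, so early output is damped
#' rather than exploding.
#'
#' @param rec An [eeg_recording()].
#' @param decay Decay factor in `(0, 1)`; 0.999 tracks statistics with a
#'   time constant of about four seconds at 250 Hz.
#' @param eps Lower bound on the denominator.
#' @return A standardized [eeg_recording()].
#' @export
ema_standardize <- function(rec, decay = 0.999, eps = 1e-4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (decay <= 0 || decay >= 1) stop("`decay` must lie in (0, 1)", call. = FALSE)
  out <- rec
  out$signal <- t(apply(rec$signal, 1L, function(x) {
    m <- as.numeric(stats::filter((1 - decay) * x, decay,
                                  method = "recursive", init = x[1L]))
    r2 <- (x - m)^2
    v <- as.numeric(stats::filter((1 - decay) * r2, decay,
                                  method = "recursive", init = 1))
    (x - m) / pmax(sqrt(v), eps)
  }))
  dimnames(out$signal) <- dimnames(rec$signal)
  out
}

#' Sliding-window trial cropping
#'
#' For every event, extracts the segment `[cue + t_start_s, cue + t_end_s)`
#' and slices it into windows of `window_samples` placed at offsets
#' `0, stride, 2*stride, ...` for as long as they fit, so each trial yields
#' `floor((segment - window) / stride) + 1` crops, all inheriting the
#' trial's label. Trials whose segment would leave the recording are
#' skipped with a warning. With the defaults (cue-relative -0.5 s to 4 s at
#' 250 Hz, 1000-sample window, stride 62) each trial yields 3 crops.
#'
#' @param rec An [eeg_recording()] (already filtered and standardized).
#' @param t_start_s,t_end_s Segment bounds in seconds relative to the cue.
#' @param window_samples Crop length in samples.
#' @param stride_samples Offset between successive crops.
#' @return A [sample_set()].
#' @export
crop_trials <- function(rec, t_start_s = -0.5, t_end_s = 4,
                        window_samples = 1000, stride_samples = 62) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  seg_len <- round((t_end_s - t_start_s) * fs)
  if (window_samples > seg_len) {
    stop("`window_samples` exceeds the trial segment length", call. = FALSE)
  }
  if (stride_samples < 1) stop("`stride_samples` must be >= 1", call. = FALSE)
  offsets <- seq(0L, seg_len - window_samples, by = stride_samples)
  n_sig <- ncol(rec$signal)
  crops <- list(); labels <- list(); trial_ids <- integer(0)
  skipped <- 0L
  for (i in seq_len(nrow(rec$events))) {
    a <- rec$events$sample[i] + round(t_start_s * fs)
    if (a < 1 || a + seg_len - 1 > n_sig) {
      skipped <- skipped + 1L
      next
    }
    for (off in offsets) {
      crops[[length(crops) + 1L]] <-
        rec$signal[, (a + off):(a + off + window_samples - 1L), drop = FALSE]
      labels[[length(labels) + 1L]] <- rec$events$label[i]
      trial_ids <- c(trial_ids, i)
    }
  }
  if (skipped) {
    warning(skipped, " trial(s) extended beyond the recording and were skipped")
  }
  n <- length(crops)
  x <- array(unlist(crops, use.names = FALSE),
             c(nrow(rec$signal), window_samples, n))
  sample_set(x, unlist(labels), trial_ids, rec$channel_names, fs)
}

#' Default preprocessing chain
#'
#' Band-pass 1-40 Hz, EMA standardization with decay 0.999, then
#' sliding-window cropping from -0.5 s to 4 s around each cue.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz,decay,t_start_s,t_end_s,window_samples,stride_samples
#'   Passed through to the pipeline stages.
#' @return A [sample_set()].
#' @export
preprocess_recording <- function(rec, low_hz = 1, high_hz = 40, decay = 0.999,
                                 t_start_s = -0.5, t_end_s = 4,
                                 window_samples = 1000, stride_samples = 62) {
  rec |>
    bandpass_filter(low_hz, high_hz) |>
    ema_standardize(decay) |>
    crop_trials(t_start_s, t_end_s, window_samples, stride_samples)
}
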