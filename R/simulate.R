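#' The 22-electrode montage of the four-class motor-imagery benchmark
#'
#' Channel names (10-20 extended positions) in recording order for the
#' standard 22-electrode, 250 Hz four-class motor-imagery setup the
#' package emulates.
#'
#' @format Character vector of length 22.
#' @export
mi_montage_22 <- c(
  "Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
  "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
  "CP3", "CP1", "CPz", "CP2", "CP4",
  "P1", "Pz", "P2", "POz"
)

.default_informative <- function(n_channels, n_classes, channel_names) {
  if (n_channels == 22L && n_classes == 4L) {
    # contralateral organization: left hand -> right motor cortex (C4),
    # right hand -> left motor cortex (C3), feet -> vertex, tongue -> FCz
    list(left_hand = match("C4", channel_names),
         right_hand = match("C3", channel_names),
         feet = match("Cz", channel_names),
         tongue = match("FCz", channel_names))
  } else {
    stats::setNames(as.list(seq_len(n_classes)),
                    paste0("class", seq_len(n_classes)))
  }
}

#' Configuration of the synthetic motor-imagery generator
#'
#' Describes a simulated recording session: four motor-imagery classes,
#' 22 channels at 250 Hz, 4.5-second trials (0.5 s pre-cue + 4 s task) and
#' 72 trials per class by default, matching the geometry of the standard
#' four-class benchmark. Every channel carries pink background noise, white
#' sensor noise and a narrowband mu rhythm (band-limited noise, 8-13 Hz);
#' during the task window of a trial of class `k`, the rhythm amplitude on
#' that class's informative channels is multiplied by `1 - erd_depth`
#' (event-related desynchronization), so the band power drops by the
#' factor `(1 - erd_depth)^2`.
#'
#' @param n_channels Number of electrodes.
#' @param sampling_rate_hz Sampling rate.
#' @param trial_seconds Trial span including the 0.5 s pre-cue baseline.
#' @param n_trials_per_class Trials per class.
#' @param n_classes Number of classes.
#' @param informative_channels Named list mapping class name to the channel
#'   indices that desynchronize for that class.
#' @param erd_band_hz Length-2 band of the simulated rhythm (Hz).
#' @param erd_depth Fractional amplitude reduction in `(0, 1)`.
#' @param rhythm_rms_uv Baseline RMS amplitude of the rhythm (microvolts).
#' @param pink_rms_uv,white_rms_uv RMS of the 1/f background and white
#'   sensor noise.
#' @param pink_exponent Spectral exponent alpha of the 1/f^alpha background.
#' @param gap_seconds Inter-trial rest gap.
#' @param channel_names Electrode names (defaults to [mi_montage_22] when
#'   `n_channels == 22`).
#' @param seed Integer seed making the recording reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 22, sampling_rate_hz = 250,
                       trial_seconds = 4.5, n_trials_per_class = 72,
                       n_classes = 4, informative_channels = NULL,
                       erd_band_hz = c(8, 13), erd_depth = 0.5,
                       rhythm_rms_uv = 15, pink_rms_uv = 10,
                       white_rms_uv = 1, pink_exponent = 1,
                       gap_seconds = 2, channel_names = NULL,
                       seed = 20200220) {
  if (n_channels < 1 || n_trials_per_class < 1 || n_classes < 2) {
    stop("channel, trial and class counts must be positive (>= 2 classes)",
         call. = FALSE)
  }
  if (erd_depth <= 0 || erd_depth >= 1) {
    stop("`erd_depth` must lie in (0, 1)", call. = FALSE)
  }
  if (trial_seconds <= 0.5) {
    stop("`trial_seconds` must exceed the 0.5 s pre-cue baseline", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 22L) mi_montage_22 else
      paste0("ch", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels) {
    stop("`channel_names` must have length `n_channels`", call. = FALSE)
  }
  if (is.null(informative_channels)) {
    informative_channels <- .default_informative(n_channels, n_classes,
                                                 channel_names)
  }
  if (length(informative_channels) != n_classes) {
    stop("`informative_channels` needs one entry per class", call. = FALSE)
  }
  idx <- unlist(informative_channels)
  if (any(idx < 1 | idx > n_channels)) {
    stop("informative channel indices must lie in 1..n_channels", call. = FALSE)
  }
  structure(
    list(n_channels = as.integer(n_channels),
         sampling_rate_hz = sampling_rate_hz,
         trial_seconds = trial_seconds,
         n_trials_per_class = as.integer(n_trials_per_class),
         n_classes = as.integer(n_classes),
         informative_channels = informative_channels,
         erd_band_hz = erd_band_hz, erd_depth = erd_depth,
         rhythm_rms_uv = rhythm_rms_uv, pink_rms_uv = pink_rms_uv,
         white_rms_uv = white_rms_uv, pink_exponent = pink_exponent,
         gap_seconds = gap_seconds, channel_names = channel_names,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# 1/f^alpha noise via spectral shaping of white noise, scaled to unit RMS
.pink_noise <- function(n, alpha) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  i <- 0:(n - 1)
  f <- pmin(i, n - i)                     # two-sided frequency index
  shape <- c(0, f[-1L]^(-alpha / 2))      # DC removed
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a synthetic motor-imagery recording
#'
#' Builds one continuous recording of all trials in randomized class order,
#' separated by rest gaps, with an event marker at every cue onset. The
#' generating process is fully determined by `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `recording` (an [eeg_recording()]) and
#'   `ground_truth` (class labels per trial and the class-to-channel map).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$sampling_rate_hz
  nyq <- fs / 2
  pre <- round(0.5 * fs)
  trial_len <- round(cfg$trial_seconds * fs)
  gap_len <- round(cfg$gap_seconds * fs)
  n_trials <- cfg$n_trials_per_class * cfg$n_classes
  classes <- names(cfg$informative_channels)
  labels <- sample(rep(classes, each = cfg$n_trials_per_class))
  total <- gap_len + n_trials * (trial_len + gap_len)

  trial_starts <- gap_len + (seq_len(n_trials) - 1L) * (trial_len + gap_len) + 1L
  events <- tibble::tibble(sample = trial_starts + pre,
                           label = factor(labels, levels = classes))

  bf <- signal::butter(4, cfg$erd_band_hz / nyq, type = "pass")
  # task-window envelope: one column per class, 1 except during that
  # class's task windows where amplitude drops to (1 - erd_depth)
  att <- 1 - cfg$erd_depth
  env <- matrix(1, total, cfg$n_classes, dimnames = list(NULL, classes))
  task_len <- trial_len - pre
  for (i in seq_len(n_trials)) {
    on <- events$sample[i]
    env[on:(on + task_len - 1L), labels[i]] <- att
  }

  sig <- matrix(0, cfg$n_channels, total)
  for (ch in seq_len(cfg$n_channels)) {
    pink <- .pink_noise(total, cfg$pink_exponent) * cfg$pink_rms_uv
    white <- stats::rnorm(total, sd = cfg$white_rms_uv)
    mu <- signal::filtfilt(bf, stats::rnorm(total))
    mu <- mu / stats::sd(mu) * cfg$rhythm_rms_uv
    e <- rep(1, total)
    for (k in seq_along(classes)) {
      if (ch %in% cfg$informative_channels[[k]]) {
        e <- e * env[, k]
      }
    }
    sig[ch, ] <- pink + white + mu * e
  }
  rownames(sig) <- cfg$channel_names

  truth <- structure(
    list(informative_channels = lapply(cfg$informative_channels,
                                       function(i) cfg$channel_names[i]),
         trial_labels = events$label, seed = cfg$seed),
    class = "mi_ground_truth"
  )
  list(recording = eeg_recording(sig, cfg$channel_names, fs, events),
       ground_truth = truth)
}

#' Generate a preprocessed synthetic sample set
#'
#' [generate_recording()] composed with the default preprocessing chain
#' (band-pass 1-40 Hz, EMA standardization with decay 0.999, cue-relative
#' cropping). The crop window spans the task portion of the trial
#' (4 s = 1000 samples by default) and the 0.5 s pre-cue slack admits
#' three crops per trial at the default stride of 62 samples, so the
#' default configuration yields 864 balanced samples (216 per class).
#'
#' @param cfg A [sim_config()].
#' @param stride_samples Crop stride (default 62).
#' @return A list with elements `samples` (a [sample_set()]) and
#'   `ground_truth`.
#' @export
generate_sampleset <- function(cfg, stride_samples = 62) {
  gen <- generate_recording(cfg)
  fs <- cfg$sampling_rate_hz
  task_s <- cfg$trial_seconds - 0.5
  samples <- preprocess_recording(
    gen$recording,
    t_start_s = -0.5, t_end_s = task_s,
    window_samples = round(task_s * fs),
    stride_samples = stride_samples
  )
  list(samples = samples, ground_truth = gen$ground_truth)
}
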