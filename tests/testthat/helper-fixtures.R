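# Shared fixtures, all generated in code.

# A small synthetic session: fewer trials than the default study geometry
# but the same montage, rate and trial structure, so pipelines stay cheap.
small_mi_config <- function(seed = 42, n_trials_per_class = 4, ...) {
  sim_config(n_trials_per_class = n_trials_per_class, seed = seed, ...)
}

# The high-SNR planted-channel benchmark used by the recovery experiments:
# deep ERD (80% amplitude drop) and a strong rhythm, so that channel
# information dominates the pink-noise background. Recovery tracks
# generalization, so the training recipe leans on data volume and weight
# decay rather than long schedules (see the methods vignette).
benchmark_config <- function(seed) {
  sim_config(n_trials_per_class = 24, erd_depth = 0.8, rhythm_rms_uv = 25,
             seed = seed)
}

benchmark_hp <- function(seed) {
  hyperparameters(epochs = 6, patience = Inf, weight_decay = 1e-2,
                  validation_split = 0, seed = seed)
}

# Tiny 2-class sample set with an amplitude-coded separable rule: class "a"
# carries a strong 10 Hz rhythm on channel 1, class "b" on channel 2.
toy_separable_samples <- function(n_per_class = 12, n_channels = 4,
                                  t_len = 1000, seed = 7) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(stats::rnorm(n_channels * t_len * n, sd = 0.5),
             c(n_channels, t_len, n))
  tt <- seq_len(t_len) / 250
  carrier <- sin(2 * pi * 10 * tt)
  labels <- rep(c("a", "b"), each = n_per_class)
  for (i in seq_len(n)) {
    ch <- if (labels[i] == "a") 1L else 2L
    x[ch, , i] <- x[ch, , i] + 3 * carrier
  }
  sample_set(x, labels, seq_len(n), paste0("ch", seq_len(n_channels)))
}

# Short hyperparameters for smoke-level training runs.
fast_hp <- function(epochs = 3, seed = 1, ...) {
  hyperparameters(epochs = epochs, patience = Inf, seed = seed, ...)
}

# Plain white-noise recording with evenly spaced events, for crop tests.
noise_recording <- function(n_channels = 3, n_events = 5, fs = 250,
                            trial_gap_s = 6.5, seed = 1) {
  set.seed(seed)
  n <- round((n_events + 1) * trial_gap_s * fs)
  sig <- matrix(stats::rnorm(n_channels * n), n_channels, n)
  events <- tibble::tibble(
    sample = round(seq_len(n_events) * trial_gap_s * fs - 5 * fs),
    label = factor(rep_len(c("x", "y"), n_events))
  )
  eeg_recording(sig, paste0("ch", seq_len(n_channels)), fs, events)
}
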