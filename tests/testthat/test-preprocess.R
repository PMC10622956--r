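# Signal pipeline: band-pass filtering, EMA standardization, cropping.

make_sine_recording <- function(freq_hz, fs = 250, secs = 8, n_channels = 2) {
  tt <- seq(0, secs - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(sin(2 * pi * freq_hz * tt), each = n_channels),
                n_channels, length(tt))
  eeg_recording(sig, paste0("ch", seq_len(n_channels)), fs,
                tibble::tibble(sample = integer(0), label = character(0)))
}

rms <- function(x) sqrt(mean(x^2))

test_that("band-pass keeps the pass band and rejects the stop band and DC", {
  trim <- 251:1750  # interior, away from filtfilt edge transients
  r50 <- bandpass_filter(make_sine_recording(50), 1, 40)
  expect_lt(rms(r50$signal[1, trim]), 0.1 * rms(make_sine_recording(50)$signal[1, trim]))
  r10 <- bandpass_filter(make_sine_recording(10), 1, 40)
  expect_gt(rms(r10$signal[1, trim]), 0.9 * rms(make_sine_recording(10)$signal[1, trim]))
  dc <- make_sine_recording(10)
  dc$signal[] <- 1
  rdc <- bandpass_filter(dc, 1, 40)
  expect_lt(max(abs(rdc$signal[, trim])), 0.05)
})

test_that("band-pass validates its band and preserves structure", {
  rec <- make_sine_recording(10)
  expect_error(bandpass_filter(rec, 40, 1), "band edges")
  expect_error(bandpass_filter(rec, 1, 200), "band edges")
  out <- bandpass_filter(rec, 1, 40)
  expect_identical(dim(out$signal), dim(rec$signal))
  expect_identical(out$channel_names, rec$channel_names)
  expect_identical(out$events, rec$events)
})

test_that("EMA standardization tracks mean 0 / variance 1 on stationary noise", {
  set.seed(31)
  n <- 40000
  rec <- eeg_recording(matrix(rnorm(n, mean = 5, sd = 2), 1, n), "ch1", 250,
                       tibble::tibble(sample = integer(0), label = character(0)))
  out <- ema_standardize(rec, 0.999)
  tail_q <- out$signal[1, (3 * n / 4):n]
  expect_lt(abs(mean(tail_q)), 0.1)
  expect_lt(abs(stats::var(tail_q) - 1), 0.1)
  expect_identical(dim(out$signal), dim(rec$signal))
})

test_that("EMA standardization sends constants to zero and validates decay", {
  rec <- eeg_recording(matrix(3, 2, 5000), c("a", "b"), 250,
                       tibble::tibble(sample = integer(0), label = character(0)))
  out <- ema_standardize(rec, 0.999)
  expect_lt(max(abs(out$signal[, 1000:5000])), 1e-6)
  expect_error(ema_standardize(rec, 1), "decay")
  expect_error(ema_standardize(rec, 0), "decay")
})

test_that("filtering and standardization commute with channel permutation", {
  set.seed(32)
  sig <- matrix(rnorm(4 * 2000), 4, 2000)
  ev <- tibble::tibble(sample = integer(0), label = character(0))
  rec <- eeg_recording(sig, paste0("ch", 1:4), 250, ev)
  perm <- c(3, 1, 4, 2)
  rec_p <- eeg_recording(sig[perm, ], paste0("ch", 1:4)[perm], 250, ev)
  for (f in list(function(r) bandpass_filter(r, 1, 40),
                 function(r) ema_standardize(r, 0.99))) {
    expect_equal(unname(f(rec)$signal[perm, ]), unname(f(rec_p)$signal),
                 tolerance = 1e-10)
  }
})

test_that("crop counts follow floor((L - W)/s) + 1 and match enumeration", {
  for (L in c(40, 51, 63)) {
    for (W in c(20, 33)) {
      for (s in c(1, 5, 7, 40)) {
        # brute-force placement enumeration
        placed <- 0L
        off <- 0L
        while (off + W <= L) {
          placed <- placed + 1L
          off <- off + s
        }
        expect_identical(placed, as.integer((L - W) %/% s + 1L),
                         info = paste(L, W, s))
      }
    }
  }
  rec <- noise_recording(n_events = 4)
  ss <- crop_trials(rec, -0.5, 4, window_samples = 1000, stride_samples = 62)
  expect_identical(dim(ss$x)[3], 4L * ((1125L - 1000L) %/% 62L + 1L))
})

test_that("crops stay inside their trial and inherit its label", {
  rec <- noise_recording(n_events = 5)
  ss <- crop_trials(rec, -0.5, 4, 1000, 62)
  expect_identical(sort(unique(ss$trial_ids)), 1:5)
  fs <- rec$sampling_rate
  for (i in seq_len(dim(ss$x)[3])) {
    tr <- ss$trial_ids[i]
    expect_identical(as.character(ss$labels[i]),
                     as.character(rec$events$label[tr]))
  }
  # window = segment length: exactly one crop per trial, equal to the segment
  one <- crop_trials(rec, -0.5, 4, window_samples = 1125, stride_samples = 62)
  expect_identical(dim(one$x)[3], 5L)
  a <- rec$events$sample[2] - round(0.5 * fs)
  expect_equal(one$x[, , 2], rec$signal[, a:(a + 1124)], ignore_attr = TRUE)
})

test_that("out-of-bounds trials are skipped with a warning", {
  rec <- noise_recording(n_events = 3)
  rec$events$sample[3] <- ncol(rec$signal) - 10L
  expect_warning(ss <- crop_trials(rec, -0.5, 4, 1000, 62), "skipped")
  expect_identical(sort(unique(ss$trial_ids)), 1:2)
})
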