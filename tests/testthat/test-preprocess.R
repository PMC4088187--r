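test_that("common average reference removes the cross-channel mean", {
  # worked two-channel case: (3, 1) -> (1, -1)
  rec <- eeg_recording(matrix(c(3, 1), nrow = 2), c("C3", "C4"), 250,
                       data.frame(onset_sample = 0, condition = "hand",
                                  trial_index = 1))
  out <- apply_car(rec, c("C3", "C4"))
  expect_equal(as.numeric(out$signal), c(1, -1))

  # common mode cancels exactly
  rec2 <- eeg_recording(matrix(7.5, 9, 20), analysis_channels(), 250,
                        data.frame(onset_sample = 0, condition = "hand",
                                   trial_index = 1))
  expect_true(all(apply_car(rec2)$signal == 0))

  # random matrix: per-sample mean subtraction oracle
  rec3 <- make_random_recording(1000, seed = 1)
  out3 <- apply_car(rec3)
  idx <- match(analysis_channels(), rec3$channel_labels)
  expect_lt(max(abs(colMeans(out3$signal[idx, ]))), 1e-10)
  oracle <- rec3$signal[idx, ] -
    matrix(colMeans(rec3$signal[idx, ]), 9, 1000, byrow = TRUE)
  expect_equal(out3$signal[idx, ], oracle, tolerance = 1e-12)
  # non-referenced channel untouched
  expect_equal(out3$signal["AFz", ], rec3$signal["AFz", ])

  # idempotence
  expect_equal(apply_car(out3)$signal, out3$signal, tolerance = 1e-10)

  expect_error(apply_car(rec3, c("C3", "Pz")), "unknown channel")
})

test_that("trial segmentation slices [onset, onset + length) and drops truncated trials", {
  fs <- 250
  n_trial <- 2 * fs
  sig <- matrix(as.numeric(seq_len(10 * 10 * n_trial)), nrow = 10)
  onsets <- seq(0, by = n_trial, length.out = 10)
  rec <- eeg_recording(sig, c("AFz", analysis_channels()), fs,
                       data.frame(onset_sample = onsets, condition = "hand",
                                  trial_index = 1:10))
  par <- paradigm_spec(trial_length = 2, cue_onset = 0.5, cue_offset = 1,
                       mi_window = c(1, 2), sampling_rate = fs)
  ts <- segment_trials(rec, par)
  expect_equal(dim(ts$data), c(10, 10, n_trial))
  expect_equal(ts$time_axis[1], 0)

  # round trip: concatenated slices reproduce the source exactly
  rebuilt <- do.call(cbind, lapply(1:10, function(i) ts$data[i, , ]))
  expect_identical(rebuilt, sig)

  # event whose window exceeds the recording is dropped with a warning
  rec$events <- rbind(rec$events,
                      data.frame(onset_sample = ncol(sig) - 1,
                                 condition = "hand", trial_index = 11))
  expect_warning(ts2 <- segment_trials(rec, par), "truncated")
  expect_equal(dim(ts2$data)[1], 10)
})

test_that("artifact rejection is strict at the threshold and preserves survivors", {
  dat <- array(0, c(3, 9, 100))
  dat[1, 4, 50] <- 81       # strictly above: rejected
  dat[2, 5, 10] <- 80       # exactly at threshold: kept
  dat[3, , ] <- rnorm(900, sd = 5)
  ts <- trial_set(dat, analysis_channels(), 250, c("hand", "feet", "hand"))
  res <- reject_artifacts(ts, 80)
  expect_equal(res$n_rejected, 1)
  expect_equal(res$trials$conditions, c("feet", "hand"))
  expect_identical(res$trials$data[1, , ], dat[2, , ])
  expect_identical(res$trials$data[2, , ], dat[3, , ])

  dat2 <- array(200, c(2, 9, 10))
  ts2 <- trial_set(dat2, analysis_channels(), 250, c("hand", "hand"))
  expect_warning(res2 <- reject_artifacts(ts2, 80), "all 2 trials")
  expect_equal(dim(res2$trials$data)[1], 0)
})

test_that("injected artifacts are caught at the generator's flagged rate", {
  par <- paradigm_spec()
  prof <- participant_profile("P", n_trials_per_condition = 50)
  rec <- generate_participant(prof, par, seed = 3, conditions = "hand",
                              artifact_fraction = 0.1)
  pre <- preprocess_recording(rec, par)
  # oracle: the injector's own flags
  expect_equal(pre$n_rejected, sum(rec$artifact_trials))
  # flagged count within the binomial 99% interval around 10% of 50
  expect_gte(sum(rec$artifact_trials), qbinom(0.005, 50, 0.1))
  expect_lte(sum(rec$artifact_trials), qbinom(0.995, 50, 0.1))
  # clean trials stay under the rejection threshold
  prof2 <- participant_profile("P", n_trials_per_condition = 5)
  rec2 <- generate_participant(prof2, par, seed = 4)
  expect_lt(max(abs(rec2$signal)), 80)
})

test_that("band-pass is zero-phase, selective, and linear", {
  fs <- 250
  alpha <- default_bands()$alpha
  tr10 <- make_sine_trials(freq = 10, amp = 1, dur = 4, fs = fs)
  out10 <- bandpass(tr10, alpha)
  mid <- 300:700
  # passband identity (amplitude and phase preserved away from edges)
  expect_lt(max(abs(out10$data[1, 1, mid] - tr10$data[1, 1, mid])), 0.05)

  # stopband: 40 Hz residual < 10% RMS
  tr40 <- make_sine_trials(freq = 40, amp = 1, dur = 4, fs = fs)
  out40 <- bandpass(tr40, alpha)
  expect_lt(sqrt(mean(out40$data[1, 1, mid]^2)),
            0.1 * sqrt(mean(tr40$data[1, 1, mid]^2)))

  # one octave outside the passband: >= 20 dB attenuation
  tr26 <- make_sine_trials(freq = 26, amp = 1, dur = 4, fs = fs)
  out26 <- bandpass(tr26, alpha)
  expect_lt(sqrt(mean(out26$data[1, 1, mid]^2)), 10^(-20 / 20))

  # zero in, zero out
  trz <- make_sine_trials(amp = 0, dur = 2, fs = fs)
  expect_true(all(bandpass(trz, alpha)$data == 0))

  # linearity: filter(a x + b y) = a filter(x) + b filter(y)
  set.seed(9)
  x <- array(rnorm(2 * 1 * 500), c(2, 1, 500))
  y <- array(rnorm(2 * 1 * 500), c(2, 1, 500))
  mk <- function(d) trial_set(d, "C3", fs, rep("hand", 2))
  lhs <- bandpass(mk(2 * x - 3 * y), alpha)$data
  rhs <- 2 * bandpass(mk(x), alpha)$data - 3 * bandpass(mk(y), alpha)$data
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)

  expect_error(bandpass(tr10, band_definition("bad", 100, 130)), "Nyquist")
})
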