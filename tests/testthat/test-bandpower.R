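alpha <- default_bands()$alpha

test_that("sliding RMS matches closed forms", {
  # constant-amplitude sinusoid: RMS = A / sqrt(2)
  tr <- make_sine_trials(freq = 10, amp = 10, dur = 4, band = alpha)
  bp <- band_power(tr, window = 1)
  mid <- 300:700
  expect_lt(max(abs(bp$values[1, 1, mid] - 10 / sqrt(2))) / (10 / sqrt(2)),
            0.02)

  # zero signal -> zero series
  trz <- make_sine_trials(amp = 0, dur = 2, band = alpha)
  expect_true(all(band_power(trz)$values == 0))

  # degenerate one-sample window: |x(t)| exactly
  set.seed(4)
  d <- array(rnorm(1 * 1 * 300), c(1, 1, 300))
  trr <- trial_set(d, "C3", 250, "hand", band = alpha)
  bp1 <- band_power(trr, window = 1 / 250)
  expect_equal(bp1$values[1, 1, ], abs(d[1, 1, ]), tolerance = 1e-12)

  expect_error(band_power(trr, window = 10), "longer than trial")
})

test_that("baseline correction subtracts the per-trial pre-cue mean", {
  set.seed(11)
  vals <- array(rnorm(3 * 2 * 1000, mean = 5), c(3, 2, 1000))
  ser <- smrphase:::feature_series(vals, (0:999) / 250, "bandpower")
  out <- baseline_correct(ser, c(0, 1.5))
  idx <- 1:375
  for (tr in 1:3) for (ch in 1:2) {
    expect_lt(abs(mean(out$values[tr, ch, idx])), 1e-10)
    # oracle: direct subtraction
    expect_equal(out$values[tr, ch, ],
                 vals[tr, ch, ] - mean(vals[tr, ch, idx]),
                 tolerance = 1e-12)
  }
  # sign convention: baseline 5, MI value 3 -> -2 (desynchronization)
  v2 <- array(5, c(1, 1, 1000)); v2[1, 1, 500] <- 3
  s2 <- smrphase:::feature_series(v2, (0:999) / 250, "bandpower")
  o2 <- baseline_correct(s2, c(0, 1.5))
  expect_equal(o2$values[1, 1, 500], -2 + (5 - mean(v2[1, 1, 1:375])),
               tolerance = 1e-9)
})

test_that("channel averaging equals the explicit mean and commutes with baselining", {
  set.seed(12)
  vals <- array(rnorm(2 * 9 * 500), c(2, 9, 500))
  ser <- smrphase:::feature_series(vals, (0:499) / 250, "bandpower",
                                   channel_labels = analysis_channels())
  avg <- average_channels(ser)
  oracle <- apply(vals, c(1, 3), mean)
  expect_equal(avg$values[, 1, ], oracle, tolerance = 1e-12)

  # (x, -x) cancels
  v2 <- array(0, c(1, 2, 100))
  v2[1, 1, ] <- sin(1:100); v2[1, 2, ] <- -sin(1:100)
  s2 <- smrphase:::feature_series(v2, (0:99) / 250, "bandpower",
                                  channel_labels = c("C3", "C4"))
  expect_true(all(abs(average_channels(s2, c("C3", "C4"))$values) < 1e-15))

  # commutes with baseline correction
  a <- baseline_correct(average_channels(ser), c(0, 1.5))
  b <- average_channels(baseline_correct(ser, c(0, 1.5)))
  expect_equal(a$values, b$values, tolerance = 1e-10)

  expect_error(average_channels(s2, analysis_channels()), "missing channel")
})

test_that("segment means reduce to the four 2-s windows", {
  fs <- 250
  ta <- (0:(8 * fs - 1)) / fs
  cs <- smrphase:::feature_series(array(3.3, c(1, 1, length(ta))), ta,
                                  "bandpower")
  expect_equal(unname(segment_means(cs)), rep(3.3, 4))

  ramp <- smrphase:::feature_series(array(ta, c(1, 1, length(ta))), ta,
                                    "bandpower")
  expect_equal(unname(segment_means(ramp)), c(1, 3, 5, 7),
               tolerance = 1 / fs)

  set.seed(13)
  v <- array(rnorm(2 * 1 * length(ta)), c(2, 1, length(ta)))
  rs <- smrphase:::feature_series(v, ta, "bandpower")
  got <- segment_means(rs)
  tm <- colMeans(rbind(v[1, 1, ], v[2, 1, ]))
  oracle <- vapply(list(c(0, 2), c(2, 4), c(4, 6), c(6, 8)),
                   function(w) mean(tm[ta >= w[1] & ta < w[2]]), 0)
  expect_equal(unname(got), oracle, tolerance = 1e-12)

  short <- smrphase:::feature_series(array(1, c(1, 1, 100)), (0:99) / fs,
                                     "bandpower")
  expect_error(segment_means(short), "shorter")
})

test_that("baseline power scales with amplitude and separates groups by the injected ratio", {
  tr <- make_sine_trials(freq = 10, amp = 6, n_trials = 2,
                         channels = analysis_channels(), dur = 4,
                         band = alpha)
  v <- baseline_power(tr, baseline_window = c(0, 1.5))
  expect_lt(abs(v - 6 / sqrt(2)) / (6 / sqrt(2)), 0.02)
  tr2 <- tr; tr2$data <- tr$data * 2
  expect_equal(baseline_power(tr2, baseline_window = c(0, 1.5)), 2 * v,
               tolerance = 1e-10)

  # generator ground truth: group B baseline amplitude 1.5x group A
  par <- paradigm_spec()
  stat <- function(g, amp_scale, seed) {
    prof <- participant_profile(g, baseline_amp = c(alpha = 10 * amp_scale,
                                                    lower_beta = 0,
                                                    mid_beta = 0,
                                                    upper_beta = 0),
                                n_trials_per_condition = 2, noise_amp = 0.5)
    rec <- generate_participant(prof, par, seed = seed, conditions = "hand")
    pre <- preprocess_recording(rec, par)
    baseline_power(bandpass(pre$trials, alpha), par$baseline_window)
  }
  a <- vapply(1:10, function(i) stat("A", 1, 300 + i), 0)
  b <- vapply(1:10, function(i) stat("B", 1.5, 400 + i), 0)
  expect_lt(abs(mean(b) / mean(a) - 1.5), 0.15)
})
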