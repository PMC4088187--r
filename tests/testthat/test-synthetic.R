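par_default <- paradigm_spec()

test_that("profile and paradigm invariants are enforced", {
  expect_error(participant_profile("P", erd_depth = 1.2), "erd_depth")
  expect_error(participant_profile("P", plv_target = -0.1), "plv_target")
  expect_error(participant_profile("P", switch_rate = 0), "switch_rate")
  expect_error(participant_profile("P", n_trials_per_condition = 0),
               "n_trials")
  expect_error(paradigm_spec(sampling_rate = 50), "60 Hz")
  expect_error(paradigm_spec(cue_onset = 4, cue_offset = 3), "cue_onset")
  tb <- default_template_bank()
  expect_equal(rowSums(tb$transition_matrix), rep(1, 6), tolerance = 1e-12)
  expect_true(all(tb$offsets > -pi & tb$offsets <= pi))
  expect_error(template_bank(tb$offsets, tb$transition_matrix * 2),
               "sum to 1")
})

test_that("generation is deterministic in the seed", {
  prof <- participant_profile("P", n_trials_per_condition = 2)
  r1 <- generate_participant(prof, par_default, seed = 99)
  r2 <- generate_participant(prof, par_default, seed = 99)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$events, r2$events)
  r3 <- generate_participant(prof, par_default, seed = 100)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("cohort generation yields the stated sizes and is deterministic", {
  cfg <- cohort_config(group_a = list(n_trials_per_condition = 1),
                       group_b = list(n_trials_per_condition = 1),
                       conditions = "hand")
  coh <- generate_cohort(cfg, seed = 5)
  # 12 + 14 participants, one recording and table row each
  expect_length(coh$recordings, 26)
  expect_equal(nrow(coh$participants), 26)
  expect_equal(table(coh$participants$group), table(rep(c("A", "B"),
                                                        c(12, 14))))
  coh2 <- generate_cohort(cfg, seed = 5)
  expect_identical(lapply(coh$recordings, `[[`, "signal"),
                   lapply(coh2$recordings, `[[`, "signal"))
  expect_identical(coh$participants, coh2$participants)
  expect_error(cohort_config(n_a = 1), ">= 2")
})

test_that("zero ERD leaves MI-window band power at baseline level", {
  prof <- participant_profile("P", erd_depth = 0,
                              n_trials_per_condition = 50, noise_amp = 0.5)
  rec <- generate_participant(prof, par_default, seed = 21,
                              conditions = "hand")
  pre <- preprocess_recording(rec, par_default)
  bp <- band_power(bandpass(pre$trials, default_bands()$alpha))
  avg <- average_channels(bp)
  tm <- apply(avg$values, 3, mean)
  base <- mean(tm[window_index(avg$time_axis, par_default$baseline_window)])
  mi <- mean(tm[window_index(avg$time_axis, c(3, 7.5))])
  expect_lt(abs(mi - base) / base, 0.05)
})

test_that("injected alpha ERD of 0.5 is recovered via the envelope oracle", {
  depth <- 0.5
  prof <- participant_profile("P", erd_depth = c(alpha = depth,
                                                 lower_beta = 0,
                                                 mid_beta = 0,
                                                 upper_beta = 0),
                              n_trials_per_condition = 100, noise_amp = 0.5)
  rec <- generate_participant(prof, par_default, seed = 7,
                              conditions = "hand")
  pre <- preprocess_recording(rec, par_default)
  bp <- band_power(bandpass(pre$trials, default_bands()$alpha))
  avg <- average_channels(bp)
  tm <- apply(avg$values, 3, mean)^2   # power scale (squared RMS amplitude)
  base <- mean(tm[window_index(avg$time_axis, par_default$baseline_window)])
  # fully-expressed MI window (clear of the onset ramp and trial edge)
  mi <- mean(tm[window_index(avg$time_axis, c(3.5, 7.5))])
  measured_drop <- (base - mi) / base
  # oracle: power arithmetic on the generator's amplitude envelope,
  # amplitude (1 - depth) -> power (1 - depth)^2
  expected_drop <- 1 - (1 - depth)^2
  expect_lt(abs(measured_drop - expected_drop), 0.1 * expected_drop)
})

test_that("perfect coupling with a single template gives PLV = 1 everywhere", {
  single <- template_bank(matrix(0, 1, 10,
                                 dimnames = list(NULL,
                                                 c("AFz",
                                                   analysis_channels()))),
                          matrix(1, 1, 1))
  prof <- participant_profile("P", plv_target = 1, noise_amp = 0,
                              n_trials_per_condition = 4)
  rec <- generate_participant(prof, par_default, templates = single,
                              seed = 2, conditions = "hand")
  trials <- segment_trials(rec, par_default)   # no CAR: keep raw coupling
  ph <- instantaneous_phase(bandpass(trials, default_bands()$alpha))
  plv <- plv_timecourse(ph, c("C3", "C4"))
  mid <- window_index(plv$time_axis, c(0.5, 7.5))
  expect_true(all(plv$values[1, 1, mid] > 1 - 1e-6))
})

test_that("faster template switching raises the III increment variance (group level)", {
  # temporal variance of a stationary series is mixing-rate invariant, so
  # the rate-sensitive statistic is the variance of the first differences
  stat <- function(rec) {
    mean(vapply(instability_series(rec, par_default)$per_trial,
                function(I) var(diff(I)), 0))
  }
  wins <- 0
  for (c in 1:10) {
    sa <- vapply(1:6, function(i) {
      p <- participant_profile("A", switch_rate = 8,
                               n_trials_per_condition = 2)
      stat(generate_participant(p, par_default, seed = 1000 * c + i,
                                conditions = "hand"))
    }, 0)
    sb <- vapply(1:6, function(i) {
      p <- participant_profile("B", switch_rate = 2,
                               n_trials_per_condition = 2)
      stat(generate_participant(p, par_default, seed = 2000 * c + i,
                                conditions = "hand"))
    }, 0)
    wins <- wins + (mean(sa) > mean(sb))
  }
  expect_gte(wins, 9)
})
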