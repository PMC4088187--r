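# Shared fixture builders; everything is generated in code.

fixture_fs <- 250

# Construct a phase_set directly from a trials x channels x samples array
# of phases (bypasses the Hilbert stage for analytic test cases).
make_phase_set <- function(ph, labels = NULL, fs = fixture_fs, band = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(ph)[2]))
  structure(list(phases = ph, channel_labels = labels, sampling_rate = fs,
                 time_axis = (seq_len(dim(ph)[3]) - 1) / fs, band = band,
                 conditions = rep("hand", dim(ph)[1]), participant = NULL),
            class = "phase_set")
}

# Trial set filled with per-channel sinusoids (same across trials unless
# trial_phases given: one extra phase offset per trial).
make_sine_trials <- function(freq = 10, amp = 1, n_trials = 1,
                             channels = c("A", "B"), dur = 4,
                             fs = fixture_fs, channel_phases = NULL,
                             trial_phases = NULL, band = NULL) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  if (is.null(channel_phases)) channel_phases <- rep(0, length(channels))
  if (is.null(trial_phases)) trial_phases <- rep(0, n_trials)
  data <- array(0, c(n_trials, length(channels), n))
  for (tr in seq_len(n_trials))
    for (ch in seq_along(channels))
      data[tr, ch, ] <- amp * cos(2 * pi * freq * t + channel_phases[ch] +
                                  trial_phases[tr])
  trial_set(data, channels, fs, rep("hand", n_trials), band = band)
}

# Random-signal recording over the standard montage.
make_random_recording <- function(n_samples = 1000, seed = 42,
                                  channels = c("AFz", analysis_channels()),
                                  fs = fixture_fs) {
  set.seed(seed)
  sig <- matrix(rnorm(length(channels) * n_samples, sd = 5),
                nrow = length(channels))
  eeg_recording(sig, channels, fs,
                data.frame(onset_sample = 0, condition = "hand",
                           trial_index = 1))
}

# Adjusted Rand index between two labelings (independent implementation
# for cluster-recovery oracles).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Simulate a discrete-emission HMM path (oracle-side simulator, kept
# independent of the package's fitting code).
simulate_hmm <- function(n, A, B, pi = NULL) {
  k <- nrow(A)
  if (is.null(pi)) pi <- rep(1 / k, k)
  s <- sample.int(k, 1, prob = pi)
  out <- integer(n)
  for (t in seq_len(n)) {
    out[t] <- sample.int(ncol(B), 1, prob = B[s, ])
    s <- sample.int(k, 1, prob = A[s, ])
  }
  out
}

quick_paradigm <- function(...) paradigm_spec(...)
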