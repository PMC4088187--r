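#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean over the referenced
#' channels from each of those channels. Channels outside `channels` are
#' left untouched. Idempotent.
#'
#' @param recording an [eeg_recording()].
#' @param channels labels to re-reference (default: the nine analysis
#'   channels).
#' @return the re-referenced [eeg_recording()].
#' @export
apply_car <- function(recording, channels = analysis_channels()) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(channels) < 2) stopf("CAR needs >= 2 channels")
  miss <- setdiff(channels, recording$channel_labels)
  if (length(miss) > 0)
    stopf("unknown channel label(s): %s", paste(miss, collapse = ", "))
  idx <- match(channels, recording$channel_labels)
  sub <- recording$signal[idx, , drop = FALSE]
  recording$signal[idx, ] <- sweep(sub, 2, colMeans(sub), "-")
  recording
}

#' Segment a recording into trials
#'
#' Cuts one `[onset, onset + trial_length)` slice per event. Events whose
#' window does not fit inside the recording are dropped with a warning.
#'
#' @param recording an [eeg_recording()].
#' @param paradigm a [paradigm_spec()].
#' @return a [trial_set()] with time axis anchored at fixation-cross onset.
#' @export
segment_trials <- function(recording, paradigm) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(paradigm, "paradigm_spec"))
  fs <- recording$sampling_rate
  n <- round(paradigm$trial_length * fs)
  total <- ncol(recording$signal)
  ev <- recording$events
  ok <- ev$onset_sample >= 0 & (ev$onset_sample + n) <= total
  if (any(!ok))
    warnf("dropping %d truncated trial(s)", sum(!ok))
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0) stopf("no complete trials to segment")
  data <- array(0, c(nrow(ev), nrow(recording$signal), n))
  for (i in seq_len(nrow(ev)))
    data[i, , ] <- recording$signal[, ev$onset_sample[i] + seq_len(n)]
  ts <- trial_set(data, recording$channel_labels, fs, ev$condition,
                  participant = recording$participant)
  ts$trial_index <- ev$trial_index
  ts
}

#' Reject artifact trials by amplitude threshold
#'
#' Removes every trial in which any sample on an analysis channel strictly
#' exceeds `threshold` microvolts in absolute value. Surviving trials are
#' untouched and keep their order.
#'
#' @param trials a [trial_set()].
#' @param threshold rejection threshold (microvolts, strict `>`).
#' @param channels channels evaluated (default: the nine analysis channels).
#' @return list with `trials` (the surviving [trial_set()], possibly empty)
#'   and `n_rejected`.
#' @export
reject_artifacts <- function(trials, threshold = 80,
                             channels = analysis_channels()) {
  stopifnot(inherits(trials, "trial_set"))
  if (threshold <= 0) stopf("threshold must be > 0")
  idx <- match(channels, trials$channel_labels)
  if (anyNA(idx)) stopf("analysis channel missing from trial set")
  peak <- apply(abs(trials$data[, idx, , drop = FALSE]), 1, max)
  keep <- peak <= threshold
  if (!any(keep))
    warnf("all %d trials rejected at +/-%g microvolts", length(keep), threshold)
  out <- trials
  out$data <- trials$data[keep, , , drop = FALSE]
  out$conditions <- trials$conditions[keep]
  if (!is.null(trials$trial_index)) out$trial_index <- trials$trial_index[keep]
  list(trials = out, n_rejected = sum(!keep))
}

# Squared magnitude response of an order-n Butterworth band-pass at
# frequencies f (Hz). Applying this once in the frequency domain equals a
# forward-backward (zero-phase) pass of the order-n filter.
butter_mag2 <- function(f, low, high, order = 4) {
  f0sq <- low * high
  bw <- high - low
  x <- ifelse(f == 0, Inf, (f^2 - f0sq) / (f * bw))
  1 / (1 + x^(2 * order))
}

# Zero-phase band-pass of the rows of a numeric matrix via FFT with full
# reflection padding (suppresses wrap-around transients).
bandpass_matrix <- function(x, low, high, fs, order = 4) {
  n <- ncol(x)
  xp <- cbind(x[, n:1, drop = FALSE], x, x[, n:1, drop = FALSE])
  np <- 3 * n
  f <- c(0:(ceiling(np / 2) - 1), -(floor(np / 2):1)) * fs / np
  h <- butter_mag2(abs(f), low, high, order)
  xf <- t(stats::mvfft(t(xp)))
  y <- Re(t(stats::mvfft(t(xf * rep(h, each = nrow(x))), inverse = TRUE))) / np
  y[, n + seq_len(n), drop = FALSE]
}

#' Band-pass filter a trial set
#'
#' Zero-phase band-pass into one analysis band: the squared magnitude
#' response of a 4th-order Butterworth band-pass is applied in the
#' frequency domain (reflection-padded FFT), which is the magnitude
#' response of a forward-backward Butterworth pass and introduces no group
#' delay. Stop-band attenuation one octave outside the pass-band exceeds
#' 20 dB by a wide margin.
#'
#' @param trials a [trial_set()].
#' @param band a [band_definition()].
#' @return the filtered [trial_set()] with `$band` set.
#' @export
bandpass <- function(trials, band) {
  stopifnot(inherits(trials, "trial_set"), inherits(band, "band_definition"))
  fs <- trials$sampling_rate
  if (band$high >= fs / 2)
    stopf("band edge %g Hz is not below Nyquist (%g Hz)", band$high, fs / 2)
  d <- trials$data
  out <- trials
  for (tr in seq_len(dim(d)[1]))
    out$data[tr, , ] <- bandpass_matrix(matrix(d[tr, , ], nrow = dim(d)[2]),
                                        band$low, band$high, fs)
  out$band <- band
  out
}
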