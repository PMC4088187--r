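# Centered moving RMS with edge truncation, via cumulative sums.
moving_rms <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Time-resolved band power (RMS amplitude)
#'
#' Band power is the root-mean-squared amplitude of the band-filtered EEG,
#' computed per trial and channel in a centered sliding window (truncated
#' at the trial edges).
#'
#' @param trials a band-filtered [trial_set()].
#' @param window RMS window length (s, default 1).
#' @return a `feature_series` (trials x channels x samples).
#' @export
band_power <- function(trials, window = 1.0) {
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(trials$band))
    warnf("trial set has no band metadata; expected band-filtered input")
  fs <- trials$sampling_rate
  n <- dim(trials$data)[3]
  if (window * fs > n) stopf("RMS window longer than trial")
  half <- floor(window * fs / 2)
  vals <- trials$data
  for (tr in seq_len(dim(vals)[1]))
    for (ch in seq_len(dim(vals)[2]))
      vals[tr, ch, ] <- moving_rms(trials$data[tr, ch, ], half)
  feature_series(vals, trials$time_axis, "bandpower", band = trials$band,
                 channel_labels = trials$channel_labels,
                 n_trials = dim(vals)[1])
}

#' Subtract the pre-cue baseline
#'
#' Per trial and channel, subtracts that series' scalar mean over the
#' baseline window. Negative corrected values during MI indicate
#' event-related desynchronization, positive values synchronization.
#'
#' @param series a `feature_series` (band power or PLV).
#' @param baseline_window `[start, end)` in seconds (default the 1.5 s
#'   before a cue at 1.5 s).
#' @return the baseline-corrected `feature_series`.
#' @export
baseline_correct <- function(series, baseline_window = c(0, 1.5)) {
  stopifnot(inherits(series, "feature_series"))
  idx <- window_index(series$time_axis, baseline_window)
  v <- series$values
  base <- apply(v[, , idx, drop = FALSE], c(1, 2), mean)
  series$values <- v - array(rep(base, dim(v)[3]), dim(v))
  series$baseline_corrected <- TRUE
  series$baseline_window <- baseline_window
  series
}

#' Average a feature over the nine analysis channels
#'
#' @param series a `feature_series` with a channel dimension.
#' @param channels labels to average (all must be present).
#' @return a single-channel `feature_series`.
#' @export
average_channels <- function(series, channels = analysis_channels()) {
  stopifnot(inherits(series, "feature_series"))
  idx <- match(channels, series$channel_labels)
  if (anyNA(idx))
    stopf("missing channel(s): %s",
          paste(channels[is.na(idx)], collapse = ", "))
  v <- series$values[, idx, , drop = FALSE]
  avg <- array(apply(v, c(1, 3), mean), c(dim(v)[1], 1, dim(v)[3]))
  out <- series
  out$values <- avg
  out$channel_labels <- "avg"
  out
}

#' Two-second segment means
#'
#' Averages the feature over trials first, then over each half-open time
#' segment. If the series carries a `valid_window` (PLV series exclude
#' 0.25 s at each trial edge against Hilbert edge artifacts) samples
#' outside it are ignored.
#'
#' @param series a single-channel `feature_series` covering `[0, 8)` s.
#' @param segments list of `[start, end)` windows (default 0-2, 2-4, 4-6,
#'   6-8 s).
#' @return named numeric vector, one mean per segment.
#' @export
segment_means <- function(series,
                          segments = list(`0-2` = c(0, 2), `2-4` = c(2, 4),
                                          `4-6` = c(4, 6), `6-8` = c(6, 8))) {
  stopifnot(inherits(series, "feature_series"))
  if (dim(series$values)[2] != 1)
    stopf("segment_means expects a single-channel series; average first")
  t_end <- series$time_axis[length(series$time_axis)] +
    (series$time_axis[2] - series$time_axis[1])
  hi <- max(vapply(segments, `[`, 0, 2))
  if (hi > t_end + 1e-9) stopf("series shorter than requested segments")
  tr_mean <- apply(series$values, 3, mean)   # trials averaged first
  ta <- series$time_axis
  ok <- rep(TRUE, length(ta))
  if (!is.null(series$valid_window))
    ok <- ta >= series$valid_window[1] & ta < series$valid_window[2]
  vapply(segments, function(w) {
    idx <- which(ta >= w[1] & ta < w[2] & ok)
    if (length(idx) == 0) stopf("segment [%g, %g) has no valid samples",
                                w[1], w[2])
    mean(tr_mean[idx])
  }, 0)
}

#' Absolute baseline band power
#'
#' Mean un-baselined RMS amplitude over the baseline window, the analysis
#' channels and all trials: the background-activity statistic compared
#' between groups.
#'
#' @param trials a band-filtered [trial_set()].
#' @param baseline_window `[start, end)` in seconds.
#' @param window RMS window (s).
#' @param channels channels averaged.
#' @return scalar (microvolts).
#' @export
baseline_power <- function(trials, baseline_window = c(0, 1.5),
                           window = 1.0, channels = analysis_channels()) {
  bp <- band_power(trials, window)
  idx_ch <- match(channels, bp$channel_labels)
  if (anyNA(idx_ch)) stopf("analysis channel missing")
  idx_t <- window_index(bp$time_axis, baseline_window)
  mean(bp$values[, idx_ch, idx_t])
}
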