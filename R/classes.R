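#' Motor-cortex analysis montage
#'
#' The nine channels over the sensorimotor cortex common to both recording
#' montages; all band-power averaging, pairwise phase locking and phase
#' dynamics are computed on these.
#'
#' @return character vector of nine channel labels.
#' @export
analysis_channels <- function() {
  c("FC3", "FCz", "FC4", "C3", "Cz", "C4", "CP3", "CPz", "CP4")
}

#' Reference channels for relative phase
#'
#' Channels symmetrically arranged about the midline that surround C3, Cz
#' and C4; their circular-mean phase is the reference against which the
#' relative phase vector is taken.
#'
#' @return character vector of four channel labels.
#' @export
reference_channels <- function() c("FC3", "FC4", "CP3", "CP4")

#' Analysis frequency band
#'
#' @param name one of `"alpha"`, `"lower_beta"`, `"mid_beta"`,
#'   `"upper_beta"`, or a custom label.
#' @param low,high band edges in Hz.
#' @return a `band_definition` object.
#' @export
band_definition <- function(name, low, high) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low)
    stopf("band edges must satisfy 0 < low < high (got %s-%s)", low, high)
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Default sensorimotor analysis bands
#'
#' Alpha (8-13 Hz), lower beta (13-16 Hz), mid beta (16-20 Hz) and upper
#' beta (20-30 Hz).
#'
#' @return named list of [band_definition()] objects.
#' @export
default_bands <- function() {
  list(alpha      = band_definition("alpha", 8, 13),
       lower_beta = band_definition("lower_beta", 13, 16),
       mid_beta   = band_definition("mid_beta", 16, 20),
       upper_beta = band_definition("upper_beta", 20, 30))
}

#' Trial paradigm timing
#'
#' Timing of one cue-guided motor-imagery trial. Times are seconds relative
#' to fixation-cross onset; windows are half-open `[start, end)`. The
#' baseline window is pinned to the 1.5 s immediately before the cue.
#'
#' @param trial_length trial duration (s).
#' @param cue_onset,cue_offset visual cue interval (s).
#' @param mi_window window in which motor imagery is assumed expressed at
#'   full strength (s); the generator applies its amplitude reduction here.
#' @param sampling_rate sampling rate (Hz); must exceed 60 Hz (twice the
#'   highest analysis band edge).
#' @return a `paradigm_spec` object.
#' @export
paradigm_spec <- function(trial_length = 8, cue_onset = 1.5,
                          cue_offset = 3.5, mi_window = c(2.5, 8),
                          sampling_rate = 250) {
  if (!(cue_onset >= 0 && cue_onset < cue_offset && cue_offset <= trial_length))
    stopf("need 0 <= cue_onset < cue_offset <= trial_length")
  if (sampling_rate <= 60)
    stopf("sampling_rate must exceed 60 Hz (highest analysis band is 30 Hz)")
  if (length(mi_window) != 2 || mi_window[1] >= mi_window[2] ||
      mi_window[2] > trial_length)
    stopf("mi_window must be [start, end) inside the trial")
  structure(list(trial_length = trial_length, cue_onset = cue_onset,
                 cue_offset = cue_offset, mi_window = mi_window,
                 baseline_window = c(cue_onset - 1.5, cue_onset),
                 sampling_rate = sampling_rate),
            class = "paradigm_spec")
}

#' Continuous multichannel EEG recording
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param channel_labels one label per row of `signal`.
#' @param sampling_rate Hz.
#' @param events data.frame with columns `onset_sample` (0-based),
#'   `condition` and `trial_index`.
#' @param participant optional list with `id`, `group`, `age`, `gender`,
#'   carried through segmentation.
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(signal, channel_labels, sampling_rate, events,
                          participant = NULL) {
  signal <- as.matrix(signal)
  if (nrow(signal) != length(channel_labels))
    stopf("channel_labels length (%d) != number of signal rows (%d)",
          length(channel_labels), nrow(signal))
  if (!all(c("onset_sample", "condition", "trial_index") %in% names(events)))
    stopf("events needs columns onset_sample, condition, trial_index")
  rownames(signal) <- channel_labels
  structure(list(signal = signal, channel_labels = channel_labels,
                 sampling_rate = sampling_rate, events = events,
                 participant = participant),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              nrow(x$events)))
  invisible(x)
}

#' Segmented trials
#'
#' @param data trials x channels x samples array (microvolts).
#' @param channel_labels channel labels (second dimension).
#' @param sampling_rate Hz.
#' @param conditions per-trial condition labels.
#' @param participant optional metadata list.
#' @param band optional [band_definition()] once band-filtered.
#' @return a `trial_set`; its `time_axis` starts at 0 s (fixation onset).
#' @export
trial_set <- function(data, channel_labels, sampling_rate, conditions,
                      participant = NULL, band = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[2] != length(channel_labels))
    stopf("channel dimension mismatch")
  if (dim(data)[1] != length(conditions))
    stopf("conditions length mismatch")
  structure(list(data = data, channel_labels = channel_labels,
                 sampling_rate = sampling_rate,
                 time_axis = (seq_len(dim(data)[3]) - 1) / sampling_rate,
                 conditions = conditions, participant = participant,
                 band = band),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d ch x %d samples @ %g Hz%s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate,
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

# Shared container for time-resolved features (band power, PLV).
# `values` is trials x channels x samples; either of the first two
# dimensions may be 1 after averaging. `valid_window` restricts segment
# averaging (used to drop Hilbert edge artifacts for PLV).
feature_series <- function(values, time_axis, feature, band = NULL,
                           channel_labels = NULL, n_trials = NULL,
                           baseline_corrected = FALSE, valid_window = NULL) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(time_axis))
  structure(list(values = values, time_axis = time_axis, feature = feature,
                 band = band, channel_labels = channel_labels,
                 n_trials = n_trials,
                 baseline_corrected = baseline_corrected,
                 valid_window = valid_window),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s: %d x %d x %d%s%s\n", x$feature,
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              if (!is.null(x$band)) paste0(", band ", x$band$name) else "",
              if (x$baseline_corrected) ", baselined" else ""))
  invisible(x)
}

# Index range (1-based, inclusive) of the half-open time window
# [start, end) on a 0-based-origin time axis.
window_index <- function(time_axis, window) {
  idx <- which(time_axis >= window[1] & time_axis < window[2])
  if (length(idx) == 0) stopf("window [%g, %g) contains no samples",
                              window[1], window[2])
  idx
}
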