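# Analytic signal of a real vector via the FFT Hilbert-transform method.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase via the Hilbert transform
#'
#' Per trial and channel, the angle of the analytic signal, wrapped to
#' `(-pi, pi]`. Meaningful only for narrow-band input; a warning is issued
#' when the trial set carries no band metadata.
#'
#' @param trials a band-filtered [trial_set()].
#' @return a `phase_set`: trials x channels x samples array of phases with
#'   the trial set's time axis, band and metadata.
#' @export
instantaneous_phase <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(trials$band))
    warnf("no band metadata: Hilbert phase assumes narrow-band input")
  d <- trials$data
  ph <- array(0, dim(d))
  for (tr in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2]))
      ph[tr, ch, ] <- wrap_angle(Arg(analytic_signal(d[tr, ch, ])))
  structure(list(phases = ph, channel_labels = trials$channel_labels,
                 sampling_rate = trials$sampling_rate,
                 time_axis = trials$time_axis, band = trials$band,
                 conditions = trials$conditions,
                 participant = trials$participant),
            class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat(sprintf("<phase_set> %d trials x %d ch x %d samples%s\n",
              dim(x$phases)[1], dim(x$phases)[2], dim(x$phases)[3],
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

# Edge exclusion (s) applied to PLV series before segment averaging.
plv_edge_exclusion <- 0.25

plv_series <- function(vals, phases, pair_label) {
  t_end <- phases$time_axis[length(phases$time_axis)]
  feature_series(array(vals, c(1, 1, length(vals))), phases$time_axis,
                 "plv", band = phases$band, channel_labels = pair_label,
                 n_trials = dim(phases$phases)[1],
                 valid_window = c(plv_edge_exclusion,
                                  t_end - plv_edge_exclusion))
}

#' Across-trial phase-locking value for one channel pair
#'
#' At every time point, the modulus of the trial-averaged unit phasor of
#' the inter-channel phase difference:
#' `PLV_t = |sum_n exp(i * theta(t, n))| / N` with `theta` the phase
#' difference and `N` the trial count. 1 means the phase difference is
#' identical in every trial; values near 0 mean no locking.
#'
#' @param phases a `phase_set` from [instantaneous_phase()].
#' @param pair character vector of two channel labels.
#' @return a single-pair `feature_series` with values in \[0, 1\].
#' @export
plv_timecourse <- function(phases, pair) {
  stopifnot(inherits(phases, "phase_set"), length(pair) == 2)
  idx <- match(pair, phases$channel_labels)
  if (anyNA(idx)) stopf("unknown channel in pair: %s",
                        paste(pair[is.na(idx)], collapse = ", "))
  N <- dim(phases$phases)[1]
  if (N < 2) stopf("PLV needs >= 2 trials (got %d)", N)
  dphi <- phases$phases[, idx[1], , drop = FALSE] -
    phases$phases[, idx[2], , drop = FALSE]
  dphi <- matrix(dphi, nrow = N)
  vals <- Mod(colMeans(exp(1i * dphi)))
  plv_series(vals, phases, paste(pair, collapse = "-"))
}

#' Grand-average pairwise PLV over the analysis montage
#'
#' Arithmetic mean, per time point, of the PLV time courses of all
#' `choose(9, 2) = 36` unordered pairs of the nine analysis channels.
#'
#' @param phases a `phase_set`.
#' @param channels channel labels (default: the nine analysis channels).
#' @return a pooled `feature_series` ("MC" region).
#' @export
mean_pairwise_plv <- function(phases, channels = analysis_channels()) {
  idx <- match(channels, phases$channel_labels)
  if (anyNA(idx)) stopf("missing channel(s): %s",
                        paste(channels[is.na(idx)], collapse = ", "))
  pairs <- utils::combn(channels, 2)
  acc <- 0
  for (p in seq_len(ncol(pairs)))
    acc <- acc + plv_timecourse(phases, pairs[, p])$values[1, 1, ]
  out <- plv_series(acc / ncol(pairs), phases, "MC")
  out$n_pairs <- ncol(pairs)
  out
}

#' Frontal-to-motor (M1-SMA) PLV
#'
#' Mean of the PLV time courses between one frontal channel (overlying the
#' supplementary motor area) and C3, Cz, C4. The default frontal channel is
#' FCz, the montage channel closest to the SMA; it is configurable because
#' recording montages differ in which frontal site they carry.
#'
#' @param phases a `phase_set`.
#' @param frontal frontal channel label.
#' @return a pooled `feature_series` ("M1-SMA" region).
#' @export
m1_sma_plv <- function(phases, frontal = "FCz") {
  motor <- c("C3", "Cz", "C4")
  need <- c(frontal, motor)
  if (!all(need %in% phases$channel_labels))
    stopf("missing channel(s): %s",
          paste(setdiff(need, phases$channel_labels), collapse = ", "))
  acc <- 0
  for (m in motor)
    acc <- acc + plv_timecourse(phases, c(frontal, m))$values[1, 1, ]
  plv_series(acc / 3, phases, "M1-SMA")
}
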