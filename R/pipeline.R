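#' Preprocess one recording
#'
#' Common average reference over the analysis channels, segmentation into
#' trials, and +/-80 microvolt artifact rejection, in that order.
#'
#' @param recording an [eeg_recording()].
#' @param paradigm a [paradigm_spec()].
#' @param threshold rejection threshold (microvolts).
#' @return list with `trials` (clean [trial_set()]) and `n_rejected`.
#' @export
preprocess_recording <- function(recording, paradigm, threshold = 80) {
  rec <- apply_car(recording)
  trials <- segment_trials(rec, paradigm)
  reject_artifacts(trials, threshold)
}

#' Subset a trial set by condition label
#'
#' @param trials a [trial_set()].
#' @param condition condition label to keep.
#' @return the subset [trial_set()].
#' @export
subset_trials <- function(trials, condition) {
  keep <- trials$conditions == condition
  out <- trials
  out$data <- trials$data[keep, , , drop = FALSE]
  out$conditions <- trials$conditions[keep]
  if (!is.null(trials$trial_index)) out$trial_index <- trials$trial_index[keep]
  out
}

#' Relative band-power and baseline-power feature table
#'
#' Runs the full band-power pipeline for every participant, condition and
#' band: band-pass, sliding RMS, per-trial pre-cue baselining, averaging
#' over the nine analysis channels, trial averaging and 2-s segment means.
#' Also emits the absolute pre-cue baseline power (feature
#' `baseline_power`, segment NA).
#'
#' @param cohort list with `recordings` and `participants` (as returned by
#'   [generate_cohort()] or [read_cohort()]).
#' @param paradigm a [paradigm_spec()].
#' @param bands list of [band_definition()]s.
#' @param threshold artifact-rejection threshold (microvolts).
#' @param rms_window RMS window (s).
#' @return long-format data.frame: participant, group, age, gender,
#'   n_trials, feature, condition, band, segment, value.
#' @export
compute_bandpower_table <- function(cohort, paradigm,
                                    bands = default_bands(),
                                    threshold = 80, rms_window = 1.0) {
  pt <- cohort$participants
  rows <- list()
  for (i in seq_len(nrow(pt))) {
    id <- pt$participant_id[i]
    pre <- preprocess_recording(cohort$recordings[[id]], paradigm, threshold)
    n_clean <- dim(pre$trials$data)[1]
    for (cond in unique(pre$trials$conditions)) {
      tr <- subset_trials(pre$trials, cond)
      if (dim(tr$data)[1] == 0) next
      for (b in names(bands)) {
        filt <- bandpass(tr, bands[[b]])
        bp <- band_power(filt, rms_window)
        rel <- average_channels(baseline_correct(bp, paradigm$baseline_window))
        sm <- segment_means(rel)
        for (s in names(sm))
          rows[[length(rows) + 1]] <- data.frame(
            participant = id, group = pt$group[i], age = pt$age[i],
            gender = pt$gender[i], n_trials = n_clean,
            feature = "bandpower", condition = cond, band = b, segment = s,
            value = sm[[s]])
        rows[[length(rows) + 1]] <- data.frame(
          participant = id, group = pt$group[i], age = pt$age[i],
          gender = pt$gender[i], n_trials = n_clean,
          feature = "baseline_power", condition = cond, band = b,
          segment = NA_character_,
          value = baseline_power(filt, paradigm$baseline_window, rms_window))
      }
    }
  }
  do.call(rbind, rows)
}

#' Relative PLV feature table (motor-cortex grand average and M1-SMA)
#'
#' Hilbert phases per band, across-trial PLV time courses (36-pair
#' grand average, feature `plv_MC`; frontal-to-C3/Cz/C4 mean, feature
#' `plv_M1SMA`), pre-cue baselining and 2-s segment means. The absolute
#' pre-cue PLV level is emitted as features `baseline_plv_MC` /
#' `baseline_plv_M1SMA` (time-mean over the baseline window, segment NA).
#'
#' @inheritParams compute_bandpower_table
#' @param frontal frontal channel for the M1-SMA estimate.
#' @return long-format data.frame (same schema as
#'   [compute_bandpower_table()]).
#' @export
compute_plv_table <- function(cohort, paradigm, bands = default_bands(),
                              threshold = 80, frontal = "FCz") {
  pt <- cohort$participants
  rows <- list()
  emit <- function(id, i, feature, cond, b, segment, value) {
    data.frame(participant = id, group = pt$group[i], age = pt$age[i],
               gender = pt$gender[i], n_trials = NA_integer_,
               feature = feature, condition = cond, band = b,
               segment = segment, value = value)
  }
  for (i in seq_len(nrow(pt))) {
    id <- pt$participant_id[i]
    pre <- preprocess_recording(cohort$recordings[[id]], paradigm, threshold)
    n_clean <- dim(pre$trials$data)[1]
    for (cond in unique(pre$trials$conditions)) {
      tr <- subset_trials(pre$trials, cond)
      if (dim(tr$data)[1] < 2) next
      for (b in names(bands)) {
        ph <- instantaneous_phase(bandpass(tr, bands[[b]]))
        for (reg in c("MC", "M1SMA")) {
          ser <- if (reg == "MC") mean_pairwise_plv(ph) else
            m1_sma_plv(ph, frontal)
          base_idx <- window_index(ser$time_axis, paradigm$baseline_window)
          rows[[length(rows) + 1]] <-
            emit(id, i, paste0("baseline_plv_", reg), cond, b,
                 NA_character_, mean(ser$values[1, 1, base_idx]))
          rel <- baseline_correct(ser, paradigm$baseline_window)
          sm <- segment_means(rel)
          for (s in names(sm))
            rows[[length(rows) + 1]] <-
              emit(id, i, paste0("plv_", reg), cond, b, s, sm[[s]])
        }
      }
    }
    for (j in seq_along(rows))
      if (is.na(rows[[j]]$n_trials) && rows[[j]]$participant == id)
        rows[[j]]$n_trials <- n_clean
  }
  do.call(rbind, rows)
}

#' Per-participant instability-index series
#'
#' Preprocesses one recording, filters into `band`, extracts relative
#' phases and returns the concatenated per-trial instability series for
#' one condition.
#'
#' @param recording an [eeg_recording()].
#' @param paradigm a [paradigm_spec()].
#' @param band a [band_definition()].
#' @param condition condition label.
#' @param threshold artifact threshold.
#' @return list with `I` (concatenated series), `per_trial` (list of
#'   per-trial series) and `rel` (the `relative_phase_set`).
#' @export
instability_series <- function(recording, paradigm,
                               band = default_bands()$alpha,
                               condition = "hand", threshold = 80) {
  pre <- preprocess_recording(recording, paradigm, threshold)
  tr <- subset_trials(pre$trials, condition)
  if (dim(tr$data)[1] == 0) stopf("no clean trials for condition %s",
                                  condition)
  rel <- relative_phase(instantaneous_phase(bandpass(tr, band)))
  iii <- instability_index(rel)
  per_trial <- lapply(iii, `[[`, "I")
  list(I = unlist(per_trial), per_trial = per_trial, rel = rel)
}

#' Labelled GPS symbol sequences for a cohort
#'
#' Full phase-dynamics front end: for every participant, relative phases
#' and instability index in `band` for `condition`; the GPS threshold is
#' the 50th percentile of that participant-and-condition's pooled
#' instability series; episodes are segmented per trial and summarised by
#' circular-mean patterns; patterns from the entire cohort are pooled and
#' K-means labelled (shared alphabet); per participant the episode labels
#' are concatenated in trial order into one symbol sequence.
#'
#' @param cohort list with `recordings` and `participants`.
#' @param paradigm a [paradigm_spec()].
#' @param band analysis band (default alpha).
#' @param condition condition label.
#' @param K number of K-means clusters (default 6).
#' @param percentile GPS threshold percentile (default 50).
#' @param seed RNG seed (clustering restarts).
#' @param threshold artifact threshold (microvolts).
#' @return list with `sequences` (named list of integer vectors), `groups`
#'   (named), `model` (the cluster model), `episode_counts`.
#' @export
gps_symbol_sequences <- function(cohort, paradigm,
                                 band = default_bands()$alpha,
                                 condition = "hand", K = 6, percentile = 50,
                                 seed = 1, threshold = 80) {
  pt <- cohort$participants
  all_patterns <- list()
  owner <- integer(0)
  for (i in seq_len(nrow(pt))) {
    id <- pt$participant_id[i]
    ser <- instability_series(cohort$recordings[[id]], paradigm, band,
                              condition, threshold)
    thr <- as.numeric(quantile(ser$I, percentile / 100, type = 7))
    pats <- lapply(seq_along(ser$per_trial), function(tr) {
      eps <- gps_segment(ser$per_trial[[tr]], threshold = thr)
      phi <- matrix(ser$rel$phi[tr, , ], nrow = dim(ser$rel$phi)[2])
      gps_patterns(phi, eps)
    })
    pat <- do.call(rbind, pats)
    all_patterns[[id]] <- pat
    owner <- c(owner, rep(i, nrow(pat)))
  }
  pooled <- do.call(rbind, all_patterns)
  model <- cluster_patterns(pooled, K = K, seed = seed)
  sequences <- lapply(seq_len(nrow(pt)),
                      function(i) model$labels[owner == i])
  names(sequences) <- pt$participant_id
  groups <- pt$group
  names(groups) <- pt$participant_id
  list(sequences = sequences, groups = groups, model = model,
       episode_counts = vapply(sequences, length, 0L))
}

#' End-to-end phase-dynamics group classification
#'
#' [gps_symbol_sequences()] followed by [loo_classify()].
#'
#' @inheritParams gps_symbol_sequences
#' @param candidates HMM state-count candidates per fold.
#' @param ... further arguments to [loo_classify()].
#' @return the [loo_classify()] result, plus `sequences`.
#' @export
phase_dynamics_classification <- function(cohort, paradigm,
                                          band = default_bands()$alpha,
                                          condition = "hand", K = 6,
                                          percentile = 50, seed = 1,
                                          candidates = 1:8, ...) {
  sym <- gps_symbol_sequences(cohort, paradigm, band, condition, K,
                              percentile, seed)
  res <- loo_classify(sym$sequences, unname(sym$groups), K = K,
                      candidates = candidates, seed = seed, ...)
  res$sequences <- sym$sequences
  res
}
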