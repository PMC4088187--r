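#' Synthetic participant profile
#'
#' Generative description of one participant for the synthetic EEG cohort.
#' Per-band fields may be given as a single number (recycled over the four
#' analysis bands) or as a named vector over
#' `c("alpha", "lower_beta", "mid_beta", "upper_beta")`.
#'
#' @param participant_id label.
#' @param group `"A"` or `"B"` (stand-ins for the two participant groups).
#' @param age years.
#' @param gender `"F"` or `"M"`.
#' @param n_trials_per_condition trials generated per condition (>= 1).
#' @param baseline_amp per-band oscillator amplitude (microvolts).
#' @param erd_depth per-band fractional amplitude reduction during the MI
#'   window, in \[0, 1\].
#' @param plv_target per-band inter-channel coupling level in \[0, 1\];
#'   maps monotonically onto the concentration of the per-channel phase
#'   jitter (across-trial pair PLV equals `plv_target` up to the template
#'   mixture, see the methods vignette).
#' @param switch_rate expected phase-pattern template transitions per
#'   second (> 0).
#' @param noise_amp RMS amplitude of the 1/f background (microvolts).
#' @return a `participant_profile` object.
#' @export
participant_profile <- function(participant_id, group = "A", age = 30,
                                gender = "M", n_trials_per_condition = 10,
                                baseline_amp = c(alpha = 10, lower_beta = 6,
                                                 mid_beta = 5, upper_beta = 4),
                                erd_depth = 0.4, plv_target = 0.3,
                                switch_rate = 8, noise_amp = 2) {
  bands <- names(default_bands())
  per_band <- function(x, nm) {
    if (length(x) == 1) x <- structure(rep(x, 4), names = bands)
    if (!all(bands %in% names(x)))
      stopf("%s must be scalar or named over the four analysis bands", nm)
    x[bands]
  }
  baseline_amp <- per_band(baseline_amp, "baseline_amp")
  erd_depth <- per_band(erd_depth, "erd_depth")
  plv_target <- per_band(plv_target, "plv_target")
  if (any(erd_depth < 0 | erd_depth > 1)) stopf("erd_depth must be in [0, 1]")
  if (any(plv_target < 0 | plv_target > 1)) stopf("plv_target must be in [0, 1]")
  if (switch_rate <= 0) stopf("switch_rate must be > 0")
  if (n_trials_per_condition < 1) stopf("n_trials_per_condition must be >= 1")
  structure(list(participant_id = participant_id, group = group, age = age,
                 gender = gender,
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 baseline_amp = baseline_amp, erd_depth = erd_depth,
                 plv_target = plv_target, switch_rate = switch_rate,
                 noise_amp = noise_amp),
            class = "participant_profile")
}

#' Phase-pattern template bank
#'
#' Ground-truth phase microstates for the generator: each template assigns
#' one phase offset per montage channel; switching between templates follows
#' a continuous-time Markov chain whose embedded jump chain is
#' `transition_matrix`.
#'
#' @param offsets templates x channels matrix of phase offsets (radians,
#'   wrapped to (-pi, pi]); column names are the montage labels.
#' @param transition_matrix row-stochastic jump matrix over templates.
#' @return a `template_bank` object.
#' @export
template_bank <- function(offsets, transition_matrix) {
  offsets <- as.matrix(offsets)
  K <- nrow(offsets)
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(K, K)))
    stopf("transition_matrix must be %d x %d", K, K)
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stopf("transition_matrix rows must sum to 1")
  if (any(offsets <= -pi | offsets > pi))
    stopf("template offsets must lie in (-pi, pi]")
  structure(list(offsets = offsets, transition_matrix = transition_matrix),
            class = "template_bank")
}

#' Default template bank
#'
#' Six fixed, well-spread phase-offset templates over the default ten-channel
#' montage (frontal AFz plus the nine motor-cortex channels), with a uniform
#' jump chain (no self-transitions). Deterministic: the offsets are drawn
#' once under a hard-coded seed.
#'
#' @param n_templates number of templates (default 6, the K used for
#'   K-means labelling).
#' @param channels montage labels.
#' @return a [template_bank()].
#' @export
default_template_bank <- function(n_templates = 6,
                                  channels = c("AFz", analysis_channels())) {
  nc <- length(channels)
  offsets <- with_seed(20140709, {
    matrix(runif(n_templates * nc, -pi, pi), nrow = n_templates)
  })
  offsets[offsets <= -pi] <- pi
  colnames(offsets) <- channels
  tm <- matrix(1 / (n_templates - 1), n_templates, n_templates)
  diag(tm) <- 0
  template_bank(offsets, tm)
}

# Band centre frequencies used by the oscillator model.
band_centres <- function() {
  c(alpha = 10.5, lower_beta = 14.5, mid_beta = 18, upper_beta = 25)
}

# 1/f ("pink") noise, generated by FFT spectral shaping of white noise and
# scaled to unit RMS.
pink_noise <- function(n) {
  white <- rnorm(n)
  x <- fft(white)
  f <- c(seq_len(ceiling(n / 2) + 1) - 1,
         rev(seq_len(n - ceiling(n / 2) - 1)))
  scale <- 1 / sqrt(pmax(f, 1))
  y <- Re(fft(x * scale, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Per-channel phase-jitter scales for an across-trial pair PLV of `p`
# (PLV = exp(-(s0^2 + s1^2)) for two independent channels). The total
# variance is split into a per-trial constant offset (s0: sets the PLV
# without broadening the oscillator spectrum) and a small within-trial
# AR(1) component (s1, capped at 0.4 rad) that drives the moment-to-moment
# phase dynamics.
jitter_sigma <- function(p) {
  p <- pmin(pmax(p, 1e-6), 1)
  tot2 <- -log(p)
  s1sq <- pmin(tot2 / 2, 0.4^2)
  list(s0 = sqrt(tot2 - s1sq), s1 = sqrt(s1sq))
}

# Sample one continuous-time template chain over a trial: exponential
# holding times at `rate`, jumps by the embedded chain. Returns a
# per-sample template index vector.
sample_template_chain <- function(templates, rate, n_samples, fs) {
  K <- nrow(templates$offsets)
  if (K == 1) return(rep(1L, n_samples))
  t_end <- n_samples / fs
  states <- sample.int(K, 1)
  times <- 0
  repeat {
    t_next <- times[length(times)] + rexp(1, rate)
    if (t_next >= t_end) break
    s_cur <- states[length(states)]
    states <- c(states, sample.int(K, 1,
                                   prob = templates$transition_matrix[s_cur, ]))
    times <- c(times, t_next)
  }
  states[findInterval((seq_len(n_samples) - 1) / fs, times)]
}

#' Generate one synthetic participant recording
#'
#' Builds a continuous multichannel EEG recording as a sum of four
#' band-limited amplitude-modulated oscillators riding on 1/f noise.
#' Within each band, all channels share a slowly drifting base phase; each
#' channel adds the phase offset of the currently active template plus a
#' smooth (AR(1)) wrapped-Gaussian jitter whose scale is set by
#' `plv_target`. On every trial the oscillator amplitude drops by
#' `erd_depth` inside the paradigm's MI window (raised-cosine ramps).
#' Identical `(profile, paradigm, templates, seed)` give bit-identical
#' output.
#'
#' @param profile a [participant_profile()].
#' @param paradigm a [paradigm_spec()].
#' @param templates a [template_bank()]; its channel count must match the
#'   montage.
#' @param seed integer seed; all randomness is derived from it.
#' @param channels montage labels (>= the nine analysis channels plus one
#'   frontal channel).
#' @param conditions condition labels cycled over trials.
#' @param artifact_fraction fraction of trials that receive a +/-100
#'   microvolt square transient (exercises the rejection stage).
#' @param artifact_amp artifact amplitude (microvolts).
#' @param template_bands bands whose oscillators carry the template phase
#'   offsets (default alpha: the phase-microstate dynamics are modelled as
#'   a mu-rhythm phenomenon; the random phase jumps of template switching
#'   would otherwise broaden every band's spectrum and leak power across
#'   the band edges).
#' @return an [eeg_recording()]; `$artifact_trials` flags injected trials
#'   and `$switch_times` records the per-trial template switch times.
#' @export
generate_participant <- function(profile, paradigm,
                                 templates = default_template_bank(),
                                 seed = 1,
                                 channels = c("AFz", analysis_channels()),
                                 conditions = c("hand", "feet"),
                                 artifact_fraction = 0,
                                 artifact_amp = 100,
                                 template_bands = "alpha") {
  bands <- default_bands()
  fs <- paradigm$sampling_rate
  if (fs <= 2 * max(vapply(bands, `[[`, 0, "high")))
    stopf("sampling rate %g Hz too low for the 20-30 Hz analysis band", fs)
  if (!all(analysis_channels() %in% channels))
    stopf("montage must include the nine analysis channels")
  if (ncol(templates$offsets) != length(channels))
    stopf("template bank has %d channels, montage has %d",
          ncol(templates$offsets), length(channels))
  nc <- length(channels)
  n_trial <- round(paradigm$trial_length * fs)
  gap <- round(0.5 * fs)
  n_per_cond <- profile$n_trials_per_condition
  n_trials <- n_per_cond * length(conditions)
  fc <- band_centres()
  drift_sd <- 1.5            # rad / sqrt(s): slow base-phase wander
  # the within-trial jitter component is capped at 0.4 rad and smoothed
  # at 0.15 s so the phase-modulated oscillators stay narrow-band; PLV is
  # set mainly by the trial-constant offsets (see jitter_sigma)
  rho <- exp(-1 / (fs * 0.15))

  # MI amplitude mask with 0.5 s raised-cosine onset ramp
  tt <- (seq_len(n_trial) - 1) / fs
  ramp <- 0.5
  m <- numeric(n_trial)
  mi <- paradigm$mi_window
  up <- tt >= mi[1] & tt < mi[1] + ramp
  m[up] <- 0.5 * (1 - cos(pi * (tt[up] - mi[1]) / ramp))
  m[tt >= mi[1] + ramp & tt < mi[2]] <- 1
  if (mi[2] < paradigm$trial_length) {
    dn <- tt >= mi[2] - ramp & tt < mi[2]
    m[dn] <- pmin(m[dn], 0.5 * (1 + cos(pi * (tt[dn] - (mi[2] - ramp)) / ramp)))
    m[tt >= mi[2]] <- 0
  }

  with_seed(seed, {
    cond_seq <- sample(rep(conditions, each = n_per_cond))
    total <- gap + n_trials * (n_trial + gap)
    signal <- matrix(0, nc, total)
    onset <- integer(n_trials)
    switch_times <- vector("list", n_trials)
    artifact <- rep(FALSE, n_trials)
    sig <- jitter_sigma(profile$plv_target)

    for (tr in seq_len(n_trials)) {
      start <- gap + (tr - 1) * (n_trial + gap)   # 0-based onset
      onset[tr] <- start
      tpl <- sample_template_chain(templates, profile$switch_rate, n_trial, fs)
      switch_times[[tr]] <- which(diff(tpl) != 0) / fs
      x <- matrix(0, nc, n_trial)
      for (b in names(bands)) {
        amp <- profile$baseline_amp[[b]]
        if (amp <= 0) next
        env <- amp * (1 - profile$erd_depth[[b]] * m)
        base <- runif(1, -pi, pi) + 2 * pi * fc[[b]] * tt +
          cumsum(rnorm(n_trial, 0, drift_sd / sqrt(fs)))
        s0 <- sig$s0[[b]]; s1 <- sig$s1[[b]]
        tpl_b <- if (b %in% template_bands) tpl else rep(1L, n_trial)
        off_b <- if (b %in% template_bands) templates$offsets else
          matrix(0, 1, nc)
        for (ch in seq_len(nc)) {
          jit <- rnorm(1, 0, s0)   # trial-constant coupling offset
          if (s1 > 0) {
            e <- rnorm(n_trial, 0, s1 * sqrt(1 - rho^2))
            e[1] <- rnorm(1, 0, s1)
            jit <- jit + as.numeric(stats::filter(e, rho, method = "recursive"))
          }
          x[ch, ] <- x[ch, ] +
            env * cos(base + off_b[tpl_b, ch] + jit)
        }
      }
      for (ch in seq_len(nc))
        x[ch, ] <- x[ch, ] + profile$noise_amp * pink_noise(n_trial)
      signal[, start + seq_len(n_trial)] <- x
    }
    # inter-trial background (columns outside every trial window)
    in_trial <- rep(FALSE, total)
    for (tr in seq_len(n_trials)) in_trial[onset[tr] + seq_len(n_trial)] <- TRUE
    idx_bg <- which(!in_trial)
    for (ch in seq_len(nc))
      signal[ch, idx_bg] <- profile$noise_amp * rnorm(length(idx_bg))

    if (artifact_fraction > 0) {
      artifact <- runif(n_trials) < artifact_fraction
      for (tr in which(artifact)) {
        ch <- sample(match(analysis_channels(), channels), 1)
        at <- sample.int(n_trial - round(0.2 * fs), 1)
        idx <- onset[tr] + at + seq_len(round(0.2 * fs))
        signal[ch, idx] <- signal[ch, idx] + sample(c(-1, 1), 1) * artifact_amp
      }
    }

    events <- data.frame(onset_sample = onset, condition = cond_seq,
                         trial_index = seq_len(n_trials))
    rec <- eeg_recording(signal, channels, fs, events,
                         participant = list(id = profile$participant_id,
                                            group = profile$group,
                                            age = profile$age,
                                            gender = profile$gender))
    rec$artifact_trials <- artifact
    rec$switch_times <- switch_times
    rec
  })
}

#' Two-group cohort specification
#'
#' Group-level generative settings for [generate_cohort()]. `group_a` and
#' `group_b` are lists overriding the per-group defaults below; see
#' [participant_profile()] for field meanings. The defaults state a
#' two-group world mirroring the contrasts of interest: group B carries
#' 1.5x the baseline oscillator amplitude, about half the MI amplitude
#' reduction, higher background coupling, and a 4x slower phase-pattern
#' switch rate than group A.
#'
#' @param n_a,n_b participants per group (defaults 12 and 14).
#' @param group_a,group_b per-group parameter overrides.
#' @param paradigm a [paradigm_spec()].
#' @param templates a [template_bank()].
#' @param conditions condition labels generated per participant.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(n_a = 12, n_b = 14, group_a = list(),
                          group_b = list(), paradigm = paradigm_spec(),
                          templates = default_template_bank(),
                          conditions = c("hand", "feet")) {
  if (n_a < 2 || n_b < 2) stopf("each group needs >= 2 participants")
  def_a <- list(baseline_amp = c(alpha = 10, lower_beta = 6, mid_beta = 5,
                                 upper_beta = 4),
                erd_depth = c(alpha = 0.5, lower_beta = 0.2, mid_beta = 0.4,
                              upper_beta = 0.35),
                plv_target = 0.30, switch_rate = 8, noise_amp = 2,
                n_trials_per_condition = 10,
                age_mean = 26, age_sd = 3, p_female = 5 / 12)
  def_b <- list(baseline_amp = c(alpha = 15, lower_beta = 9, mid_beta = 7.5,
                                 upper_beta = 6),
                erd_depth = c(alpha = 0.25, lower_beta = 0.1, mid_beta = 0.15,
                              upper_beta = 0.12),
                plv_target = 0.45, switch_rate = 2, noise_amp = 3,
                n_trials_per_condition = 10,
                age_mean = 36, age_sd = 11, p_female = 0.5)
  structure(list(n_a = n_a, n_b = n_b,
                 group_a = utils::modifyList(def_a, group_a),
                 group_b = utils::modifyList(def_b, group_b),
                 paradigm = paradigm, templates = templates,
                 conditions = conditions),
            class = "cohort_config")
}

#' Generate a two-group synthetic cohort
#'
#' Draws per-participant ages and genders from the group settings, derives
#' one sub-seed per participant from the master seed, and generates every
#' recording with [generate_participant()]. Deterministic in `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed master seed.
#' @return list with `recordings` (named list of [eeg_recording()]) and
#'   `participants` (data.frame: participant_id, group, age, gender,
#'   n_trials).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- config$n_a + config$n_b
  seeds <- derive_seeds(seed, n_total + 1)
  groups <- c(rep("A", config$n_a), rep("B", config$n_b))
  meta <- with_seed(seeds[n_total + 1], {
    lapply(seq_len(n_total), function(i) {
      g <- if (groups[i] == "A") config$group_a else config$group_b
      list(age = max(18, min(65, round(rnorm(1, g$age_mean, g$age_sd)))),
           gender = if (runif(1) < g$p_female) "F" else "M")
    })
  })
  recordings <- vector("list", n_total)
  ids <- sprintf("P%02d", seq_len(n_total))
  for (i in seq_len(n_total)) {
    g <- if (groups[i] == "A") config$group_a else config$group_b
    prof <- participant_profile(
      participant_id = ids[i], group = groups[i], age = meta[[i]]$age,
      gender = meta[[i]]$gender,
      n_trials_per_condition = g$n_trials_per_condition,
      baseline_amp = g$baseline_amp, erd_depth = g$erd_depth,
      plv_target = g$plv_target, switch_rate = g$switch_rate,
      noise_amp = g$noise_amp)
    recordings[[i]] <- generate_participant(prof, config$paradigm,
                                            config$templates, seeds[i],
                                            conditions = config$conditions)
  }
  names(recordings) <- ids
  participants <- data.frame(
    participant_id = ids, group = groups,
    age = vapply(meta, `[[`, 0, "age"),
    gender = vapply(meta, `[[`, "", "gender"),
    n_trials = vapply(recordings, function(r) nrow(r$events), 0L))
  list(recordings = recordings, participants = participants)
}
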