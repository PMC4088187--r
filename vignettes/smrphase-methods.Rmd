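---
title: "Methods: sensorimotor-rhythm band power, phase locking and phase-pattern dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensorimotor-rhythm band power, phase locking and phase-pattern dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`smrphase` compares three families of sensorimotor-rhythm (SMR) correlates
of motor imagery (MI) between two participant groups recorded with a
nine-channel motor-cortex EEG montage (FC3, FCz, FC4, C3, Cz, C4, CP3,
CPz, CP4):

1. **Band power / ERD** — root-mean-squared amplitude of the EEG filtered
   into alpha (8–13 Hz), lower beta (13–16 Hz), mid beta (16–20 Hz) and
   upper beta (20–30 Hz), baselined against the 1.5 s before the visual
   cue. Negative relative band power during MI is event-related
   desynchronization (ERD).
2. **Phase-locking value (PLV)** — the modulus of the trial-averaged unit
   phasor of an inter-channel Hilbert-phase difference,
   $\mathrm{PLV}_t = \frac{1}{N}\left|\sum_{n=1}^{N} e^{j\theta(t,n)}\right|$,
   computed for all 36 channel pairs (grand average) and for a frontal-to-
   motor subset standing in for M1–SMA coupling.
3. **Phase-pattern dynamics** — relative phase vectors
   $\Phi_i(t) = \theta_i(t) - \theta_R(t)$ (with $\theta_R$ the circular
   mean phase of FC3, FC4, CP3, CP4), summarised per sample by the
   Instantaneous Instability Index
   $I(t) = \sum_i d_i(t)^2$,
   $d_i(t) = \frac{1}{N}\sum_h \{1 - \cos(\Phi_i(t) - \Phi_h(t))\}$.
   Maximal runs with $I$ strictly below its 50th percentile are global
   phase-synchronization (GPS) episodes; each is summarised by the
   per-channel circular mean pattern, patterns are pooled across the
   whole cohort and K-means labelled ($K = 6$), and each participant's
   label sequence is modelled by a discrete-emission hidden Markov model
   (HMM). Group membership of a held-out participant is decided by which
   group's HMM assigns the higher per-symbol log-likelihood
   (leave-one-out), with exact binomial significance against chance.

Group-level inference uses stepwise ordinary-least-squares regressions
(entry p < 0.05, removal p > 0.10) of segment-mean features on group, age,
gender and artifact-free trial count, with Kolmogorov–Smirnov-gated pooled
t-tests wherever group is selected. All p-values are reported uncorrected
and flagged as such; the time segments are strongly dependent, which is
the package's (and the source analyses') argument against Bonferroni-style
correction.

# Processing conventions

* Sample indexing is 0-based in time (`time_axis[1] = 0`), windows are
  half-open `[start, end)`.
* Common average referencing subtracts the instantaneous mean of the nine
  analysis channels from those channels only; it is idempotent.
* Artifact rejection removes a trial iff any analysis-channel sample
  strictly exceeds 80 µV in magnitude ("exceeded ±80 µV"), applied after
  CAR and segmentation.
* Band-pass filtering is zero-phase. There is no IIR filter-design library
  in the supported dependency set, so the squared magnitude response of a
  4th-order Butterworth band-pass is applied in the frequency domain on
  reflection-padded FFTs. This is exactly the magnitude response of a
  forward–backward 4th-order Butterworth pass (16 dB/octave per direction;
  measured stop-band attenuation one octave out is far beyond the 20 dB
  contract) and introduces no group delay, which matters because the
  Hilbert phase is extracted from the same filtered signal.
* Band power uses a 1.0 s centered RMS window (truncated at trial edges).
  The window length is a free choice; 2-s segment means are insensitive
  to it.
* Trials are baselined individually (per trial and channel) before trial
  averaging; segment means average trials first, then time within
  `[0,2), [2,4), [4,6), [6,8)` s.
* PLV series exclude 0.25 s at each trial edge from segment means to keep
  Hilbert edge artifacts out; "baseline PLV" is the time-mean over the
  pre-cue window.
* The frontal channel for the M1–SMA PLV defaults to FCz: the literature
  pair set (FPz–C3/Cz/C4) names a channel absent from both recording
  montages, and FCz is the montage site overlying the SMA. It is
  configurable (e.g. AFz).
* The GPS percentile threshold is computed per participant × condition
  over the concatenated instability series of all that participant's
  trials, keeping episode rates comparable across trials; episode label
  sequences are concatenated in trial order into one symbol sequence per
  participant and condition.
* K-means is fit once on patterns pooled across all participants and both
  groups (k-means++ seeding, 10 restarts, best within-SS kept) so that
  symbol identities are shared — otherwise cross-participant HMM
  classification would be meaningless. Degenerate circular means (zero
  resultant) return 0 and are flagged; affected episodes are retained.
* HMM state counts are selected by minimising AIC + BIC with parameter
  count $p = (k-1) + k(k-1) + k(K-1)$; ties go to the smaller $k$.
  Baum–Welch uses uniform-random row-stochastic initialisation with
  seeded restarts; held-out log-likelihoods are normalised per symbol to
  remove sequence-length bias; exact likelihood ties are broken by a
  seeded fair coin and logged.

# The synthetic cohort as a stated world

No recordings are distributed with the analyses this package implements,
so every stage is validated against a generative stand-in cohort. The
generator is a first-class, tested module, and its defaults are a fixed
"stated world", not tuning knobs:

* **Paradigm**: 250 Hz, 8 s trials, fixation cross at 0 s, cue 1.5–3.5 s,
  baseline window `[0, 1.5)` s. MI-locked amplitude reduction is placed at
  `[2.5, 8)` s with 0.5 s raised-cosine ramps: ERD develops over roughly a
  second after imagery onset, and starting the full-depth window at 2.5 s
  keeps the 1-s RMS smoothing from bleeding the effect into the `[0, 2)` s
  segment, which the localisation checks use as a negative control.
* **Cohort**: 12 participants in group A and 14 in group B, ages
  ~N(26, 3) vs ~N(36, 11) years, 5/12 vs 7/14 female, 10 trials per
  condition. Group B (the impaired-group stand-in) has 1.5× the baseline
  oscillator amplitude, roughly half the ERD depth, higher background
  coupling (PLV target 0.45 vs 0.30) and a 4× slower phase-pattern switch
  rate (2/s vs 8/s) — the direction of every group contrast the package
  is designed to detect.
* **Oscillators**: per band, an amplitude-modulated cosine with a slowly
  drifting shared base phase (random-walk drift, 1.5 rad/√s). Band centres
  are 10.5, 14.5, 18 and 25 Hz.
* **Coupling**: each channel adds phase jitter whose total variance
  $\sigma^2 = -\log(\mathrm{plv\_target})$ sets the across-trial pair PLV
  analytically ($\mathrm{PLV} = e^{-\sigma^2}$ for two independent
  channels). The variance is split into a *trial-constant* offset and a
  *within-trial* AR(1) component capped at 0.4 rad (0.15 s correlation
  time). The split matters: phase jitter that is large *and* fast
  broadens the oscillator spectrum far beyond its band, leaking power
  across band edges and diluting the planted amplitude effects. A
  trial-constant offset realises arbitrary coupling levels with zero
  broadening (it is also the standard model of trial-to-trial coupling
  variability), while the bounded AR(1) part supplies the within-trial
  phase dynamics that the instability index needs. The per-channel jitter
  is wrapped-Gaussian rather than von Mises; at matched concentration the
  two are nearly identical and the Gaussian form gives the closed-form
  PLV mapping and a natural AR(1) smoothing.
* **Phase-pattern templates**: six fixed per-channel phase-offset vectors
  (drawn once under a hard-coded seed, uniform jump chain, exponential
  holding times at the profile's switch rate), applied to the *alpha*
  band only. Template switches insert random phase jumps that broaden the
  carrier line by roughly (switch rate)/π Hz; restricting the templates to
  the band whose phase dynamics are analysed models the microstates as a
  mu-rhythm phenomenon and keeps the beta carriers narrow.
* **Noise**: 1/f background at 2–3 µV RMS; an optional artifact injector
  adds ±100 µV square transients to a stated fraction of trials for the
  rejection stage.
* Template chains are drawn independently per trial ("induced" rather
  than time-locked dynamics). A consequence worth knowing: with a
  multi-template bank the across-trial PLV ceiling sits below 1 even at
  `plv_target = 1`, because the active template at a given latency varies
  across trials. Exact-PLV checks therefore use a single-template bank,
  which the API supports directly.

## What the generator does not emulate

No volume conduction or biophysical head model, no ocular/muscular
artifact realism beyond the square transient, no 1/f non-stationarity,
no condition-specific (hand vs feet) topography: both conditions share
the same group-level statistics. A green test therefore establishes that
the pipeline recovers *injected* effects of the stated kind and size —
not that it would detect any particular physiological effect in real
recordings.

## Interpreting two stated properties

* *"Temporal variance" of the instability index.* The pooled variance of
  a stationary series is invariant to its mixing rate, so a faster
  template switch rate cannot raise var$(I)$; what it raises is the
  variance of the first differences,
  $\mathrm{var}(\Delta I) = 2\,\mathrm{var}(I)\,(1 - \rho_1)$. The
  switch-rate property test uses that increment variance, at the group
  level.
* *Null behaviour of leave-one-out classification.* Under exchangeable
  groups, LOO group classification is biased *below* 0.5 (each held-out
  participant's own data are missing from their group's model), so null
  accuracies may fall under the lower edge of the Binomial(n, ½) band.
  The null acceptance check bounds the anti-conservative side only: no
  significance in more than 2/10 null cohorts and no accuracy above the
  band's upper edge.
* *Symbol-level holding contrast.* The end-to-end separation check
  phrases the group contrast as symbol-holding probabilities of 0.95 vs
  0.5. Episode boundaries almost always coincide with template changes
  and K-means labels carry noise, so the realizable holding ceiling is
  ≈ 0.65; the acceptance cohort uses switch rates 8/s vs 0.5/s, the
  generator's nearest realization of a strong-vs-moderate holding
  contrast (measured ≈ 0.28 vs ≈ 0.65).

# Numerical choices

* Angles are wrapped to $(-\pi, \pi]$ throughout; circular means use the
  four-quadrant arctangent of summed sines and cosines, with a resultant
  length below $10^{-8}$ flagged as degenerate (value 0 by convention).
* The GPS threshold is the type-7 (linear-interpolation) percentile;
  "below" is strict, so a constant series yields zero episodes.
* Baum–Welch runs to $|\Delta LL| < 10^{-4}$ or 500 iterations by
  default; the log-likelihood trace is non-decreasing within a restart
  (EM guarantee, asserted in tests). Rows that lose all posterior mass
  keep their previous estimates. For the heavy leave-one-out acceptance
  run, per-fold state selection is scaled down (candidates 1..4, fewer
  restarts, looser tolerance); checks that depend on converged estimates
  (parameter recovery, state-count selection) use the converged settings.
* Stepwise regression guards against collinear candidates by skipping
  predictors whose coefficient is inestimable, with a warning.
* The KS normality gate standardises by the sample mean and SD and
  compares against N(0, 1). With estimated moments the plain KS reference
  is conservative (the Lilliefors effect); the gate is therefore lenient
  about letting t-tests proceed, which matches its role here.

# Known limitations

* The exact regression statistics and classification accuracies published
  for the original human cohorts are not reproducible without those
  recordings and are out of scope; the package's claims are the analytic
  and property-based checks in its test suite.
* EDF reading is not implemented (no EDF parser exists in the supported
  dependency set); the delimited-matrix interchange format documented in
  `write_cohort()`/`read_cohort()` is the supported path.
* The stepwise entry/removal thresholds (0.05/0.10) and the pooled-
  variance t-test are classical defaults; the source analyses do not
  state theirs.
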