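# smrphase

Sensorimotor-rhythm (SMR) analysis of motor-imagery (MI) EEG for
**two-group comparisons**: event-related desynchronization (ERD) band
power, phase-locking values (PLV), and phase-pattern dynamics modelled by
K-means-labelled phase microstates and discrete hidden Markov models
(HMMs). It is aimed at BCI/neurophysiology researchers who want a tested,
end-to-end re-implementation of this analysis stack, together with a
deterministic synthetic-cohort generator so that every stage can be
validated without access to human recordings.

## The statistics at the core

* **Relative band power** — RMS amplitude of the EEG filtered into alpha
  (8–13 Hz), lower/mid/upper beta (13–16/16–20/20–30 Hz), minus the mean
  over the 1.5 s pre-cue baseline; averaged over the nine motor-cortex
  channels (FC3, FCz, FC4, C3, Cz, C4, CP3, CPz, CP4) and reduced to 2-s
  segment means over `[0,8)` s. Negative values during MI = ERD.
* **Phase-locking value** — for Hilbert phases θ of a channel pair,
  `PLV_t = |Σ_n exp(j·θ(t,n))| / N` over the N trials: 1 means the phase
  difference repeats exactly across trials, ~0 means no locking. Computed
  for all 36 pairs (grand average) and for a frontal-to-C3/Cz/C4 subset
  (M1–SMA stand-in, frontal channel configurable, default FCz).
* **Phase-pattern dynamics** — relative phases `Φ_i(t) = θ_i(t) − θ_R(t)`
  (θ_R = circular mean of FC3, FC4, CP3, CP4), Instantaneous Instability
  Index `I(t) = Σ_i d_i(t)²` with
  `d_i(t) = mean_h {1 − cos(Φ_i − Φ_h)}`; runs of `I` strictly below its
  50th percentile are global phase-synchronization episodes, summarised by
  circular-mean patterns, pooled cohort-wide, K-means labelled (K = 6) and
  modelled per group by a discrete HMM (state count by AIC + BIC).
  Held-out participants are classified by the higher per-symbol
  log-likelihood in a leave-one-out scheme; accuracy is tested against
  chance with an exact binomial tail.
* **Group inference** — stepwise OLS regressions (entry p < 0.05, removal
  p > 0.10) of each feature cell on group/age/gender/trial-count, with
  KS-gated pooled t-tests wherever group is selected; all p-values
  uncorrected and flagged.

## Worked example

Generate a 12 + 14 synthetic cohort whose groups differ in ERD depth,
baseline amplitude, coupling and phase-pattern switch rate, then run the
band-power statistics and the phase-dynamics classification:

```r
library(smrphase)

cfg <- cohort_config(
  group_a = list(n_trials_per_condition = 6, switch_rate = 8),
  group_b = list(n_trials_per_condition = 6, switch_rate = 0.5),
  conditions = "hand")
cohort <- generate_cohort(cfg, seed = 42)

bp <- compute_bandpower_table(cohort, cfg$paradigm,
                              bands = default_bands()["alpha"])
report <- run_feature_regressions(bp[bp$feature == "bandpower", ])
report[, c("band", "segment", "selected", "r_squared", "ttest_p", "direction")]
#>    band segment selected r_squared     ttest_p direction
#> 1 alpha     0-2          0.0000000          NA      <NA>
#> 2 alpha     2-4          0.0000000          NA      <NA>
#> 3 alpha     4-6    group 0.1964930 0.023323721       B>A
#> 4 alpha     6-8    group 0.2711578 0.006383095       B>A

res <- phase_dynamics_classification(cohort, cfg$paradigm, seed = 42,
                                     candidates = 1:4, restarts_select = 2,
                                     restarts_fit = 3, max_iter = 100,
                                     tol = 1e-3)
sprintf("LOO accuracy: %.4f (exact binomial p = %.2e)", res$accuracy, res$p_value)
#> [1] "LOO accuracy: 0.9615 (exact binomial p = 4.02e-07)"
```

Reading the output: the planted alpha-ERD group difference surfaces only
in the 4–6 s and 6–8 s segments (`group` selected, r² ≈ 0.20/0.27), with
the post-hoc t-test direction `B>A` — group B's relative band power is
less negative, i.e. group B desynchronizes less. The `[0,2)` s segment,
which precedes the imagery effect, correctly selects nothing. The
phase-dynamics classifier separates the groups' switch dynamics at 96%
leave-one-out accuracy (25/26), far beyond the chance tail.

## Synthetic cohorts and I/O

`generate_participant()` / `generate_cohort()` build continuous
recordings (amplitude-modulated band-limited oscillators with analytic
PLV control, template-driven alpha phase microstates, 1/f noise, optional
±100 µV artifact transients). `write_cohort()` / `read_cohort()` exchange
cohorts as plain TSV matrices plus `participants.tsv` / `events.tsv`.
A command-line front end is installed at `inst/cli/smrphase`
(`simulate`, `features`, `phasedyn`, `stats` subcommands).

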