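# fernpipe

Simulation and analysis of feedback-locked EEG in monetary and social
reward tasks.

## What this is for

Studies of the feedback error-related negativity (fERN/FRN) — the negative
frontocentral ERP deflection 250–400 ms after outcome feedback, larger for
monetary losses and undesired social outcomes and generated mainly in the
anterior cingulate cortex (ACC) — compare its condition modulation between
clinical groups (e.g. typically developing children vs ADHD vs ASD) across
a monetary gambling task and an observed social-dilemma task. Raw clinical
EEG of such studies is rarely shareable, so `fernpipe` provides the entire
study as reproducible code: task simulators, a synthetic high-density EEG
generator with controllable group-dependent fERN effects, the standard
preprocessing chain, the waveform statistics, and spherical-model source
analysis — each stage independently testable against analytic oracles.

The statistical core is:

* a **bootstrap Monte Carlo test** of the pointwise condition difference of
  two sets of waveforms: the observed pooled-variance two-sample *t* at each
  timepoint of the 250–400 ms window is referred to a null distribution
  built by resampling the pooled sample with replacement B = 5000 times
  (two-sided p = (1 + #{|t*| ≥ |t|})/(1 + B)), with temporal extents,
  peak-difference t/p/Cohen's d, and a familywise omnibus p from the null
  max-|t|;
* a **depth-weighted L2 minimum-norm inverse**
  Ĵ = WGᵀ(GWGᵀ + λC)⁻¹Y with w_i = ‖g_i‖^(−2γ), γ = 0.8, on an analytic
  three-shell spherical head model (conductivities 1 : 1/80 : 1), with
  ACC-ROI scalars compared between groups by Mann-Whitney U and effect size
  r = |Z|/√N.

## Worked example

```r
library(fernpipe)

# rigged social task: exact 72.5% / 67.5% policies
s <- simulate_pdg_session(pdg_config(), seed = 1)
sum(s$trials$fair_action == "cooperate")   # 116  (of 160 trials)
sum(s$trials$unfair_action == "betray")    # 108

# a scaled two-group cohort, monetary task only
cfg <- study_config(
  groups = c(control = 20, ADHD = 20), tasks = "IGT",
  igt = igt_config(n_trials_per_version = 20, block_len = 10),
  n_scalp = 8, fs = 256, noise_rms = 10 / sqrt(8),
  igt_policy = "uniform-random", run_source = FALSE, seed = 1)
res <- run_study(cfg)
print(res)
```

```
<fern_study> control=20, ADHD=20 subjects; tasks: IGT; seed 1
  control  IGT/DD: omnibus p = 0.015, extents 254-348 ms
  control  IGT/highfreq: omnibus p = 0.033, extents 281-332 ms
  ADHD     IGT/DD: omnibus p = 0.376
  ADHD     IGT/highfreq: omnibus p = 0.164, extents 266-273 ms
```

The control cohort shows a significant loss-vs-win fERN difference inside
the component window for both the disadvantageous-deck and the
high-loss-frequency contrasts (familywise omnibus p < 0.05 with significant
temporal extents); the ADHD cohort, whose generator applies no condition
modulation, does not reach omnibus significance — its short 266–273 ms
"extent" illustrates why pointwise extents are descriptive and detection
decisions use the omnibus p. `summary(res$contrasts$control$IGT$DD)`
prints the pointwise t/p curves; with `run_source = TRUE` the report also
contains per-subject ACC activations and between-group Mann-Whitney
contrasts.

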