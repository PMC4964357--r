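---
title: "Simulating and analysing feedback-locked EEG in monetary and social reward tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing feedback-locked EEG in monetary and social reward tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fernpipe)
```

## Scope and model

`fernpipe` implements a complete, testable pipeline for studies of the
feedback error-related negativity (fERN, also called FRN or MFN): a negative
frontocentral ERP deflection 250–400 ms after outcome feedback, larger for
losses and undesired social outcomes, and generated chiefly in the anterior
cingulate cortex (ACC). The pipeline covers five stages:

1. **Task simulation.** A two-deck, two-version child adaptation of the Iowa
   Gambling Task (160 trials per version, initial capital 120 currency
   units, cumulative feedback every 20 choices), and an observed, rigged
   Prisoner's Dilemma Game (160 trials, cumulative display every 40): the
   fair player cooperates on exactly 72.5% of trials, the unfair player
   betrays on exactly 67.5%, and the participant earns 3 points when the
   fair player cooperates versus 6 when he betrays.
2. **EEG synthesis.** Feedback-locked responses forward-projected from an
   ACC-proxy dipole through an analytic three-shell spherical head model,
   plus 1/f noise and optional blink transients.
3. **Preprocessing.** Downsample to 256 Hz, zero-phase 0.5–20 Hz bandpass,
   averaged-mastoid re-reference, epochs −200..800 ms, baseline −200..0 ms,
   threshold-based artifact rejection.
4. **Waveform statistics.** Condition averages, Fz mean amplitude in
   250–400 ms, and a bootstrap Monte Carlo test of the pointwise condition
   difference (5000 resamples), with temporal extents, peak-difference
   t/p/Cohen's d, and an omnibus max-|t| p value.
5. **Source analysis.** Depth-weighted (exponent 0.8) orientation-constrained
   L2 minimum-norm estimates on a layered spherical cortical proxy, ACC-ROI
   scalars, and Mann-Whitney group contrasts with effect size
   r = |Z|/√N.

## The synthetic generator: what it emulates, and what it does not

The generator is the package's study population. Three group profiles fix
the condition gains of the feedback-locked template:

| profile | monetary task | social task |
|---|---|---|
| control | loss > win | betrayal > cooperation |
| ADHD | no modulation (uniformly reduced) | no modulation |
| ASD | loss > win | cooperation > betrayal (inverted) |

The template is a negative Gaussian-windowed deflection (peak 310 ms,
SD 45 ms, −4 µV at Fz for unit gain, calibrated in the averaged-mastoid
reference used by the analysis; modulated conditions use gain 1.0,
non-modulated 0.6) radiating from a radial dipole at a deep frontal-midline
location. Between-subject amplitude heterogeneity is lognormal with SD 0.2
on the log scale. Background noise has 1/f-plus-white-floor power (default
RMS 10 µV per channel, independent across channels); blinks are
frontal-weighted 300 ms transients of 250 µV at a default rate of 0.03 Hz.

The generator deliberately omits several features of real recordings:
spatially correlated background sources, additional ERP components (P2,
P3), reaction-time and learning dynamics, non-stationary noise, realistic
anatomy, and channel-specific artifacts. Consequently, passing recovery
tests demonstrates that the *analysis chain* is correct and calibrated
under the stated signal model — not that the chain is robust to every
pathology of real data.

## Numerical and design choices

* **Epoch convention.** Half-open windows: −200..800 ms at 256 Hz is exactly
  256 samples, with −200 ms included and 800 ms excluded; the fERN window
  250–400 ms is likewise half-open. This removes endpoint double-counting
  ambiguity.
* **Filters.** Butterworth corner frequencies (4th-order high-pass at
  0.5 Hz, 4th-order low-pass at 20 Hz) applied zero-phase. The
  forward-backward response (the squared magnitude) is applied spectrally
  after 4 s reflection padding, which is numerically robust at very low
  normalized cutoffs and leaves component latencies untouched. Decimation is
  preceded by an anti-alias low-pass at 0.4 × the target rate.
* **Artifact rejection** is a deterministic threshold rule (peak-to-peak
  150 µV, gradient 75 µV/sample, both configurable, with a manual override
  hook). The thresholds are declared defaults of this package, not values
  taken from any particular laboratory.
* **Bootstrap null.** The null distribution resamples the *pooled* epochs
  with replacement into the original group sizes — a bootstrap null rather
  than a permutation null; a permutation variant is available via
  `analysis_config(null_method = "permutation")` for sensitivity analysis.
  Monte Carlo p values use the add-one convention (1 + #)/(1 + B), so they
  are never exactly zero. Testing is two-sided. No correction is applied
  across timepoints for the reported temporal extents (they are descriptive,
  as is standard for this component); cohort-level *detection decisions*
  instead use the omnibus max-|t| p value, whose familywise type-I error is
  calibrated at α by construction.
* **Sampling unit of the within-group contrast.** `run_study()` defaults to
  trial-level pooling across a group's subjects, which reproduces the large
  effective sample sizes implied by published fERN t/d statistics; a
  subjects-as-units alternative (per-subject condition means) is exposed via
  `test_unit = "subjects"` and is the conservative choice when
  between-subject amplitude variability dominates.
* **Head model.** The forward model is an analytic concentric-sphere solution
  (brain/skull/scalp conductivity ratio 1 : 1/80 : 1; radii 80/85/90 mm)
  computed per spherical-harmonic degree by an exact boundary solve, in
  normalized radii for conditioning, truncated at degree 60 (relative
  truncation error < 1e−6 for all supported source depths). It preserves the
  linear-inverse mathematics of realistic BEM pipelines at desk scale. The
  source space is a layered spherical sheet (radii 35/50/65 mm: a deep
  non-cortical proxy, a medial-wall/cingulate depth, and the convexity) with
  radial orientations; the ACC ROI is the anterior midline sector of the two
  cortical sheets (40–70 mm radius, |x| < 20 mm, anterior, above the axial
  plane) — a geometric definition, since mesh-based ROI extents are
  template-specific.
* **Localization metrics.** The resistive skull layer spatially smooths
  scalp topographies, so the gain-norm contrast across depth is modest and
  the minimum-norm *peak* keeps a superficial preference even with depth
  weighting; peak errors are reported for localization quality (ACC-depth
  sources localize within 25 mm under weak regularization), while the
  benefit of γ = 0.8 over γ = 0 is quantified by the squared-estimate mass
  centroid, which depth weighting moves systematically closer to deep
  sources. Noiseless probes use a weak-regularization configuration
  (assumed SNR 100), consistent with λ → 0 as noise → 0.
* **Inverse.** Tikhonov-regularized minimum norm with source-covariance
  weights ‖g‖^(−2γ), γ = 0.8 by default; λ = trace(GWGᵀ)/(n_ch · SNR²) with
  assumed SNR 3; optional baseline-interval noise covariance shrunk 10%
  towards identity. ROI activation in study reports is sign-aligned with the
  fERN generator so that the typical loss-minus-win contrast is positive.
* **Degenerate inputs.** Zero-variance data give t = 0 rather than NaN;
  all-tied Mann-Whitney inputs yield a flagged degenerate report; a zero
  pooled SD makes Cohen's d an explicit NA with a reason attribute.
* **Seeding.** Every stochastic stage takes an explicit seed; `run_study()`
  derives per-subject, per-stage seeds deterministically from the master
  seed, so reports are exactly reproducible.

## Problem sizes used in the shipped simulations

Cohort-level batteries (in the test suite and the acceptance script) use
variance-preserving downscaling chosen as this package's desk-scale study
conditions: trial counts are reduced k-fold relative to the full tasks and
trial noise is reduced √k-fold, so every subject's condition-mean SNR
matches the full design, and the trial-level test's noncentrality depends
(to first order) only on the subject count. Group sizes follow the study
design (22 control, 19 ADHD, 28 ASD). The control power battery uses mild
scaling (k = 2: 80 trials/version, 7.1 µV noise) because the unscaled
between-subject amplitude spread makes aggressive scaling slightly
conservative; the ADHD null-calibration battery is scale-free and uses
k = 8, and the social-task sign battery uses 24 trials (k ≈ 6.7).
Batteries use an 8+2-channel montage and 256 Hz synthesis, since only the
Fz channel enters waveform statistics; source-analysis checks use 64+2
channels and 750 sources.

## Known limitations

* The spherical head model shares geometry between synthesis and inversion
  (an "inverse crime"); localization figures quantify the estimator's
  behaviour under its own forward model, not anatomical accuracy.
* Independent-channel noise makes scalp topographies cleaner than real data;
  rejection thresholds were set for this regime.
* The bootstrap null's calibration is verified empirically for the shipped
  sample sizes; very small groups (< 5 units) rely on the add-one p bound.
* No ocular regression/ICA, no bad-channel interpolation, no cluster-based
  multiple-comparison correction — all deliberately out of scope.

## A minimal session

```{r example, eval = FALSE}
cfg <- study_config(
  groups = c(control = 20, ADHD = 20), tasks = "IGT",
  igt = igt_config(n_trials_per_version = 20, block_len = 10),
  n_scalp = 8, fs = 256, noise_rms = 10 / sqrt(8),
  igt_policy = "uniform-random", run_source = FALSE, seed = 1)
res <- run_study(cfg)
print(res)
summary(res$contrasts$control$IGT$DD)
```
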