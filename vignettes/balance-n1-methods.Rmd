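---
title: "Methods: detecting and predicting N1 potentials before balance corrections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and predicting N1 potentials before balance corrections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(balanceN1)
```

## The analysis model

The pipeline treats a continuous standing-balance task (nine 20 s trials
under sway-referenced support gains 0, 0.4, 2.0, 0, 0.6, −0.4, 0, 1.0,
−1.0; anterior–posterior axis only) as a sequence of naturally occurring
instability events, each with a cortical and a biomechanical signature.

**Biomechanical side.** COP velocity is the three-point central difference
`v[i] = (x[i+1] − x[i−1])·fs/2`, chosen because it introduces no time
shift and is exact for locally quadratic trajectories; the series ends use
one-sided differences so the channel keeps its length. An instability
event is a local extremum of |COPv| exceeding a subject-specific threshold
— `k·SD` of COPv over the first 20 s quiet-stance trial, `k = 3` —
followed by the first sign change of COPv, the early sign of the
corrective response. The stability context is summarized by the distance
from COP to the anatomical foot boundary in the current direction of
motion (DTB) and the time to reach it at the current speed
(TTB = DTB/|COPv|).

**Cortical side.** The cleaned fronto-central independent component is
baseline-corrected by subtracting its −5..0 s pre-task mean; the pre-task
SD is the amplitude yardstick. Per event, the N1 is the most negative
local trough at least `2·SD` below baseline within −250..−100 ms before
the zero-crossing; events without a qualifying trough are dropped. All
other ≥ 2 SD troughs become control epochs. Both classes are epoched at
−300..+100 ms around their centers, and each epoch is reduced to four
features: the median absolute COPv, shear force, head acceleration and TTB
over −300..−50 ms before the center (the window ends 50 ms early because
vestibular afference needs that long to reach cortex; the median rather
than the mean resists outliers, with the mean available via
`feature_stat = "mean"`).

**Prediction protocol.** Class imbalance (~1:2) is handled by uniform
undersampling of the majority class. Evaluation is leave-one-subject-out:
a balanced test set from the left-out subject, a balanced pool of the
remaining subjects, hyperparameter selection by mean accuracy over an
inner stratified 5-fold cross-validation (gradient-boosted trees, binary
logistic objective; depths 2–10, 60–220 rounds, learning rates
0.001/0.01/0.1), refit, and evaluation by accuracy, sensitivity and
rank-based AUC. Ten repeats per subject redraw the undersampling and the
folds. Feature attribution uses Shapley values: xgboost's exact TreeSHAP
for production, and the package's own subset-enumeration implementation
(`shap_values_exact`) in double precision — feasible because there are at
most four features — which serves as the numerical reference
(additivity holds to machine accuracy; the float32 TreeSHAP path is
cross-checked against it).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `copv_k_sd` | 3 | SD | event threshold over quiet stance, giving ≈ 6 cm/s for a quiet COPv SD of 2 cm/s |
| `n1_k_sd` | 2 | SD | trough depth criterion relative to pre-task baseline |
| `n1_search_window_ms` | (−250, −100) | ms | physiological N1 lead time before the corrective zero-crossing |
| `epoch_window_ms` | (−300, +100) | ms | saved context around each center |
| `feature_window_ms` | (−300, −50) | ms | start configurable −350..−250; end fixed at −50 (vestibular latency) |
| `ttb_eps_cm_s`, `ttb_cap_s` | 0.1 cm/s, 10 s | — | guard the division at near-zero velocity; a stationary COP has unbounded TTB |
| `refractory_s` | 1.0 | s | one excursion, one event (see below) |
| `control_exclusion_ms`, `control_min_sep_ms` | 300, 400 | ms | keep control epochs disjoint from N1 epochs and from each other (deeper trough wins) |

Two defaults deviate from the most literal reading of the detector
description. The **refractory period is 1.0 s** rather than 0.5 s: the
destabilizing-plus-corrective excursion spans ~0.9 s, and a 0.5 s
refractory can accept the corrective lobe as a second event whenever sway
noise shifts the first accepted peak early; 1 s covers one excursion while
true events are ≥ 1.5 s apart. And the **zero-crossing is localized at
the first sample of opposite (or zero) sign** with no sub-sample
interpolation: 10 ms resolution is ample for 100–250 ms windows.
Tie-breaks are deterministic everywhere: equal-depth troughs resolve to
the earliest; equal inner-CV accuracy resolves to the shallower tree, then
fewer rounds, then the smaller learning rate.

## What the synthetic cohort emulates

The generator (`cohort_params`, `generate_cohort`) reproduces the
*statistical structure* the detectors assume, not the physiology:

* **Sway.** COP velocity is a colored (Ornstein–Uhlenbeck, τ = 0.3 s)
  process of SD 2 cm/s, soft-saturated at 5.5 cm/s — physiological sway
  speeds are bounded, and the saturation keeps spontaneous sway from
  crossing the 3 SD event threshold — and leakily integrated to position
  (reversion time 8 s). A slow overdamped drift (0.03 Hz, SD 1.6 cm in
  quiet stance) scales as `1 + 0.5·|gain|`: sway-referencing inflates slow
  postural drift while barely changing fast sway speed. The quiet COPv SD
  of 2 cm/s makes the subject threshold "typically around 6 cm/s".
* **Events.** Each instability is one full sine cycle of COP velocity
  (period 0.8 s, peak 12 cm/s ± 15%): a destabilizing lobe, a sign change
  (the ground-truth zero-crossing), and a corrective lobe returning COP to
  its starting point. Event times are Poisson draws reweighted by
  `(|lean| + 0.3)^3` — losses of balance are far more likely while the COP
  is displaced from center, which both concentrates events in
  destabilizing-gain trials and couples low TTB to the instability class —
  thinned to ≥ 1.5 s separation, and confined to trials after the first
  (reference) quiet trial so the threshold is estimated from genuinely
  quiet sway. The pulse pushes in the lean direction unless too little
  room remains before the boundary. A 12 cm/s peak (not smaller) keeps
  the miss probability of the 3 SD detector at the percent level; the
  full-cycle shape returns COP home so the recording never leaves the
  stability zone (a hard clamp 2 mm inside the boundaries guards the
  Gaussian tails).
* **EEG-like trace.** The IC is band-limited (0.1–15 Hz) 1/f noise, unit
  pre-task SD. Each event gets an inverted Gaussian trough (FWHM 80 ms) of
  depth 4.5 baseline-SD at a latency drawn from N(165, 10²) ms before its
  zero-crossing; at 3 SD the −2 SD detection criterion would fail ~16% of
  the time against the background, defeating recovery testing, so the
  default sits deeper while remaining "low-amplitude" relative to
  perturbation-evoked responses. Distractor troughs of comparable depth
  (2.8–5.2 SD, 0.02 Hz) are injected away from events; most control
  epochs, however, come from the 1/f background itself, which is what
  produces the ~2:1 control:instability ratio.
* **Peripheral channels.** Shear force is a noisy linear function of the
  COM-acceleration proxy (second difference of COP) at 10 Hz; head
  acceleration is a noisy, weaker function of COPv generated at 80 Hz and
  decimated to 10 Hz through the same anti-aliased resampler the
  instrumentation path requires (4th-order Butterworth at 80% of the
  target Nyquist, forward–backward over a reflection-padded copy, then
  integer decimation).

Determinism: every subject draws from a stream hashed from
`(cohort seed, subject index)`; every classification run from
`(master seed, subject, repeat, feature set)`, so different feature sets
see identical test subsets, and a fixed master seed reproduces every
artifact byte for byte.

**What it does not emulate.** No raw multichannel EEG, no artifact
structure, no mediolateral axis, no fatigue or adaptation across trials,
no subject-specific sway spectra, and no relation between gain and sway
beyond the slow-drift scaling (the literature gives no quantitative
sway–gain map, so the factor `1 + 0.5·|gain|` is a free design choice).
Passing tests therefore certify the *pipeline* — detection, epoching,
features, protocol — under realistic signal structure, not any claim
about real balance data.

## Known limitations

* **COPv–TTB correlation.** TTB is DTB/|COPv| by definition, so the two
  epoch medians are hyperbolically linked; with both features strongly
  class-separated their pooled Pearson correlation is ≈ −0.8 on synthetic
  cohorts, and no physically plausible generator setting brings it under
  the 0.7 collinearity screen while preserving the required effect sizes.
  Real recordings are messier (measurement noise, richer boundary
  dynamics) and show a much weaker link. `correlation_screen` flags the
  pair as "strong", which is exactly what it is for; the remaining five
  pairs stay below 0.7.
* **Normality.** The |median| features are skewed mixtures, so the
  Shapiro–Wilk screen rejects normality on synthetic cohorts; it is
  reported, not enforced.
* **Absolute performance is not comparable to human data.** With a
  generative model this clean the combined classifier reaches ~90%
  accuracy; on real data the published protocol sits in the 70s. The
  meaningful checks are structural: chance recovery under label
  permutation, effect-size ordering, TTB dominating the Shapley
  attribution, and ALL4 ≥ each single-feature model.
* **Trough timing.** The 1/f background shifts the detected trough
  minimum by a sample or two; N1 center agreement with injected truth is
  statistical (≈ 97% within 20 ms on default cohorts), with mean latency
  recovered within a few ms.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the default ten-subject
cohort (180 s task + 5 s baseline per subject), the reduced grid
(depths {2, 6} × rounds {60, 140} × learning rates {0.01, 0.1}, still
spanning the full ranges), ten repeats per subject for the label-permuted
chance control (100 runs), and two repeats per subject per feature set for
the five-model comparison. The full grid is available via `hyper_grid()`
for larger studies.
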