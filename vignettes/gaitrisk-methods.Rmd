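---
title: "Accelerometer-based gait features and fall-risk classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerometer-based gait features and fall-risk classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Screening older adults for fall risk with clinical instruments (the
Short Physical Performance Battery, fall-history questionnaires) is
costly and does not reflect everyday movement. A hip-worn triaxial
accelerometer sampling raw accelerations at 30 Hz during a routine
400-m walk offers an inexpensive alternative: the periodic structure of
walking, and especially the variability of mediolateral (side-to-side)
hip motion, carries information about balance control.

`gaitrisk` implements the full analysis path for this idea as a tested
pipeline: simulate cohorts of labelled walking tracings, extract steady
("good") walking, compute a 52-feature battery per 10 s window, and
classify high versus low fall risk with random forests under 10-fold
cross-validation, including an ablation over 11 feature subsets and
entropy-based mean-decrease-impurity feature importance.

Subjects are labelled **high** fall risk when their SPPB total is ≤ 9
*and* they reported at least one fall in the past year, **low** when
SPPB is 10–12 with no falls; every other combination is
**intermediate** and excluded from the two-class model
(`assign_risk_labels()`).

## The synthetic-data generator

Real tracings of this kind are restricted-access, so the generator is a
first-class module: every downstream stage is exercised against signals
whose ground truth (step times, turn and pause schedule, sway
amplitudes) is known exactly.

One subject's signal is a sum of interpretable components:

* a constant per-axis **gravity baseline** (vertical baseline negative,
  ≈ −0.9 g, matching a hip-worn device's orientation);
* a **raised-cosine impulse** on the vertical axis at every step
  (width 0.35 of a step period);
* a **sinusoidal anteroposterior** component at step frequency;
* a **sinusoidal mediolateral** component at *stride* frequency (half
  the step frequency — the hip swings left on one step, right on the
  next) whose amplitude is redrawn every stride with coefficient of
  variation `ml_sway_amp_cv`;
* white Gaussian **sensor noise** per axis.

Step intervals are i.i.d. normal with a within-subject CV; the gait
phase is piecewise linear through the realized step times, so cadence
jitter propagates coherently to all oscillatory components. Every
`turn_every_m` metres of nominal progress (walking speed = cadence ×
0.6 m step length) a turn replaces the periodic components with
low-pass (< 0.8 Hz) aperiodic "wander" at 30% of their magnitude —
reduced, phase-disrupted motion, which is what a hip sensor records
while the wearer pivots 180° at a cone. Pauses gate all movement off
for `pause_duration_s`, at most once per out-and-back lap, with 0.2 s
cosine ramps at every transition. The oscillatory sum is re-centred so
each axis's tracing mean equals its baseline exactly, which pins the
cohort-level calibration of mean axis accelerations.

The high/low archetype defaults (`make_archetypes()`) encode the
group contrasts the simulator is meant to emulate: cadence 120.5 vs
124.6 steps/min (between-subject SD 15.5/16.7, truncated at 60),
vertical baseline −0.910 vs −0.881 g, step-time CV 0.05 vs 0.03, and
stride-to-stride mediolateral sway variability `ml_sway_amp_cv` 0.60 vs
0.40. The sway-variability base value deserves a note: mediolateral hip
acceleration is the least mechanically constrained of the three axes,
and its summary statistics in this population are extremely dispersed
relative to their near-zero means (signed coefficients of variation
with SDs two orders of magnitude above the mean), so a stride-to-stride
amplitude CV of 0.4, rising to 0.6 with impaired balance control, is
the realistic regime; the 1.5× ratio mirrors the direction of the group
contrast. These values were fixed once, on these grounds, and are the
conditions under which all recovery experiments run. What the generator
does **not** emulate: postural drift and device re-orientation over the
walk, harmonic structure beyond the fundamental (real vertical
accelerations carry strong harmonics), asymmetric left/right gait,
fatigue trends, and any between-subject variation other than cadence.
Passing tests therefore show that the pipeline recovers what the model
injects — not that it would perform identically on real tracings.

Reproducibility: a cohort's master seed expands into per-subject
streams as `seed + subject_index`; identical specs are bit-identical.

## Preprocessing

* **Vector magnitude** per sample: `sqrt(x² + y² + z²)`, in g.
* **Segmentation**: 10 s sliding windows (300 samples) with 50%
  overlap; only full windows are kept. Ten seconds is long enough to
  hold ~20 steps, which step/stride variability estimates need.
* **Inactivity filter**: a window is discarded iff the population
  standard deviation of its vector magnitude is *strictly* below
  0.01 g (the boundary value is retained, following the printed
  "< 0.01" convention). Population (denominator *n*) SD is pinned
  everywhere so the `RMS² = MEAN² + STD²` identity is exact.
* **Good-walking mask**: 1 s sub-windows (stride 0.5 s) are classified
  as walking iff (a) their vm SD clears the inactivity threshold,
  (b) the dominant non-DC frequency of the mean-removed vm lies in the
  locomotor band 1–3 Hz, and (c) the maximal normalized
  autocorrelation over lags 0.25–1.0 s is ≥ 0.3. Checks (b) and (c)
  are evaluated on a 2 s context centred on the sub-window — a 1 s
  piece has no sample pairs at the longest lags and only 1 Hz spectral
  resolution, into whose lowest band aperiodic wander leaks. A sample
  is walking iff **every** sub-window covering it passes: with union
  semantics the context bled "walking" roughly half a second into each
  turn, and the measured turn rejection was 0.71; with intersection it
  is ~0.96 while steady-walking retention stays ~0.99. The first and
  last 15 samples of every window are always non-walking (insufficient
  context). Because windows overlap by 50%, the union of window masks
  at the tracing level has no interior forced edges; that tracing-level
  mask is what mask-quality measurements use.
* **Acceptance**: a window contributes features iff ≥ 50% of its
  samples are walking (the threshold is configurable; no printed value
  exists for it). Accepted windows carry their maximal contiguous
  walking runs.

## Features

Eleven signal features per series (X, Y, Z, and vector magnitude MAG),
computed over the concatenated walking samples of the window; three
zero-lag Pearson cross-correlations (XY, YZ, XZ) over the same samples;
five gait measures from detected steps. Conventions the source material
leaves open were pinned as follows and are configurable where noted:

* **ACC** (autocorrelation coefficient): normalized autocorrelation at
  the *dominant period* lag `round(rate / PFREQ)`. Lag 1 at 30 Hz is
  ≈ 1 for any smooth signal and carries no gait information, whereas
  period-lag autocorrelation of quasi-periodic walking sits near 0.5,
  matching the observed scale of this feature; `acc_lag = "one"`
  selects plain lag 1.
* **COV**: the signed, unguarded ratio STD/MEAN. Near-zero means
  (typical for mediolateral acceleration) produce huge signed values —
  exactly the behaviour seen in this feature's published summaries — so
  no epsilon guard is applied; an exactly zero mean yields an infinite
  sentinel and such rows are dropped from modelling.
* **SMA**: per-series mean absolute value. The conventional tri-axial
  signal magnitude area sums three axes and cannot be computed "per
  axis"; the per-series form can.
* **ENERGY**: mean squared mean-removed sample — by Parseval's
  identity the DC-excluded spectral energy, without FFT length
  conventions leaking into values.
* **MCR**: crossings of the series mean per second (strict sign
  changes).
* **PFREQ**: argmax of the non-DC FFT magnitude of the mean-removed
  series; rectangular window, no zero-padding, ties to the lower
  frequency. Resolution is one bin (0.1 Hz at 10 s).
* **Step detection** (no printed algorithm exists; this is the
  package's own): within each contiguous walking run ≥ 2 s, band-pass
  the vertical axis to 0.5–3.5 Hz (2nd-order Butterworth, forward-
  backward), take local maxima with ≥ 0.25 s separation and height
  ≥ 0.5 × the run's band-passed SD, and refine each peak by parabolic
  interpolation. The sub-sample refinement matters: the 1/30 s grid
  alone contributes ~0.014 s of spurious step-interval SD, comparable
  to the true variability being estimated. The band brackets observed
  cadences (~2 Hz) with margin.
* **Gait measures**: step times are differences of consecutive events
  *within a run* (never across masked-out gaps, which would fabricate
  intervals); stride times are alternating-event differences, both
  parities pooled; `CADENCE = 60 / MEAN_STEP_TIME`. Windows with < 4
  events get missing gait features and are dropped only from feature
  sets that include gait columns.

## Modelling

* **Feature sets**: the 11-subset ablation — gait only; each axis ±
  gait; MAG ± gait; XYZ + cross-correlations (36 columns) ± gait (41).
* **Forests**: 500 trees, maximum depth 10, trained with `ranger`
  (single-threaded, seeded, in-bag counts kept). ranger offers Gini
  (not entropy) splitting for classification; splits therefore use
  Gini — also scikit-learn's default — while **importance** is the
  package's own mean-decrease-impurity computation with *entropy*: for
  every tree, the weighted entropy reduction of each split is
  recomputed from the tree structure and the retained in-bag sample
  weights, summed per feature, normalized per tree, then averaged
  across trees with the across-tree SD reported. Gini and entropy
  rank features near-identically (a test cross-checks the ranking
  against ranger's Gini importance).
* **Scores**: per-instance class probabilities average each tree's
  in-bag leaf class fraction (scikit-learn's `predict_proba`
  semantics), which is finer-grained than tree vote shares.
* **Cross-validation**: folds of equal size ± 1, shuffled under a
  fixed seed; metrics computed per fold and averaged, with pooled
  confusion counts and a pooled AUC reported for diagnostics. AUC is
  the rank (Mann–Whitney) statistic with midranks. The positive class
  is *low* fall risk, under which the gait-only precision sits at the
  majority-class base rate, as observed.
* **Instance unit**: the default instance is the *window*, labelled by
  its subject — with 67 subjects, window-level instances are the only
  way fold metrics are stable, and they match the apparent published
  protocol. The caveat is real and measurable: windows of one subject
  then appear in both training and test folds, and with identical
  group distributions (a label-permutation-style null) the forest can
  memorize subject signatures through between-subject cadence (SD ≈ 16
  steps/min), holding the null AUC near 0.65 rather than 0.5.
  `group_by_subject = TRUE` assigns whole subjects to folds (greedily
  balanced per class); under it the identical-archetype null sits at —
  if anything, slightly below — chance (0.37–0.47 across seeds: with
  only ~2 high-risk subjects per fold, per-fold AUCs are noisy and
  grouped CV carries the usual pessimistic bias), and the AUC measures
  generalization to unseen subjects.
  The parameter-recovery experiment (`analysis/06_sway_recovery.R`,
  and the acceptance suite) therefore uses the grouped mode; the
  ablation table uses the window-level default. Under the grouped
  protocol the injected 1.5× mediolateral sway-variability contrast
  yields an unseen-subject window-level AUC of ≈ 0.78 at these study
  conditions — the honest discriminability of that effect size; the
  same experiment evaluated window-level ungrouped reads ≈ 0.83, the
  difference being subject leakage, not signal.
* **Spot check**: default-parameter decision tree, random forest and
  SVM under the same folds, as a comparison table only.

## Numerical choices and degenerate inputs

Population SD throughout; strict inequality at the inactivity boundary;
FFT ties to the lower frequency; correlation of a constant series is
reported as 0 and flagged; constant series have undefined PFREQ/ACC
(`NA`); importance ties break lexicographically; all stochastic steps
(simulation, folds, forests) derive from explicit seeds and the
package never touches the caller's RNG state (`withr::with_seed`).

## Problem sizes

The shipped analyses and tests run, by choice, at the study's scale:
67 subjects (19/48), 320 s tracings at 30 Hz (≈ a 400-m walk at
1.25 m/s), ~60 windows per subject before filtering, 500-tree forests,
10-fold CV. The full pipeline completes in a few minutes on one CPU;
the test suite re-derives every oracle value at run time and uses
smaller cohorts where the property under test allows it.

## Known limitations

* The generator's realism limits (listed above) bound what green tests
  prove about real cohorts.
* The good-walking mask is a reconstruction of behaviour described
  only qualitatively in its source; its thresholds (band 1–3 Hz,
  autocorrelation ≥ 0.3) were set from the simulator's physics, not
  fitted to any real tracing.
* Entropy-vs-Gini split criterion (above) — importances use entropy,
  splits use Gini.
* Reported headline metrics on synthetic cohorts characterize the
  pipeline, not the published cohort; the restricted real data would
  be needed to reproduce published performance numbers.
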