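---
title: "Odour–image fusion for fruit-ripeness monitoring: models, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odour–image fusion for fruit-ripeness monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odourfusion)
```

# The problem

Metal-oxide (MOX) gas sensors are cheap and portable but non-specific and
drift-prone, and their resistance depends on ambient temperature and
humidity. In open-air fruit-ripeness monitoring — a plant in a glasshouse,
a fruit in an office — the odour signal competes with short-term
environmental variability, and the obvious second modality, a camera, fails
in its own ways: at night there is no usable image at all, and strong
backlight degrades detection. This package implements the full analysis
chain for such a bimodal system and, because the measurement campaigns such
systems produce are small and temporally structured, it pairs the chain
with a synthetic generator that reproduces exactly those structures, so the
statistical behaviour of every stage can be tested.

# The odour pipeline

## Temperature modulation and segmentation

Cycling the heater voltage (VH) through a fixed pattern induces a transient
response curve far richer than a steady-state reading. Two modulated
protocols are modelled: DAQ10 (5 min pre-heat at 5 V, then nine alternating
30 s stages over the levels 7, 5.5, 5, 6, 6.5 V with 0 V rests) and DAQ48
(20 min pre-heat, 30 s rests, 300 s active stages). The protocols save
6000 and 28,800 points at 10 Hz — the saved-data rate implied by
"10 min, 6000 points"; the acquisition hardware's internal clock is
irrelevant to the saved traces. The scheduled stages sum to 9.5 / 47.5 min;
we record the remainder as a trailing 0 V rest so that traces meet the
nominal point counts while every active stage keeps its scheduled duration
(extending the final active stage instead would make its segment twice as
long as the others and change every downstream feature). Segment boundaries
are half-open `[start, end)` in sample indices, so the five active segments
partition the active samples exactly — 300 points per level for DAQ10,
3000 for DAQ48. The pre-heat period is part of the saved trace: the point
counts only add up if it is recorded.

For the constant-heating protocol (DAQcont) there is no stage structure;
traces are cut into non-overlapping 10-minute windows and trailing partial
windows are dropped.

## Features

The per-segment features are the maximum response and response range at
the 7 V level, plus the maximum of the normalised EWMA-smoothed signal at
α ∈ {0.1, 0.01, 0.001} for all five sensors at all five levels — 85
features, or 10 when only the amplitude features are kept. The EWMA is
computed with an O(M) recursion for the numerator and denominator; a
property test keeps it within 1e−10 of the literal weighted sum. Smoothing
is per-segment with no carry-over across levels, matching the per-level
definition of the feature. DAQcont windows yield mean, standard deviation,
maximum, minimum and RMS per sensor (25 features). We use the *population*
standard deviation — the choice is not prescribed anywhere, so it is fixed
and documented here.

Min-max feature scaling is fitted on training folds only and applied to
test folds without clipping. Fitting on pooled data would leak the test
distribution into training — distribution shift between acquisition
batches is precisely one of the phenomena under study — so train-only
fitting is the contract even though it allows test values outside [0, 1].

## Environmental correction

Datasheets tabulate RS/R0 — the sensor resistance relative to the
reference condition 20 °C / 65 % RH — at a few temperature/humidity
combinations. We interpolate these points with an exact thin-plate-spline
radial basis function (no smoothing: the reference points are reproduced
to machine precision, and queries outside the grid extrapolate with a
warning). Through the voltage divider with supply VC = 5 V, the corrected
response is `Ṽout = VC / ((VC/Vout − 1)/α + 1)`. Correction applies to
sensors 2–5 only; the first sensor's datasheet lacks the table, so it
passes through unchanged. The real datasheet values are not
redistributable, so the package ships a *synthetic* but physically
plausible grid (ratios decreasing in humidity and temperature, equal to 1
at the reference condition, per-sensor slopes; see
`inst/extdata/synthetic_rs_r0_grid.csv`) and accepts user CSV overrides.
Correctness is therefore established by round-trip recovery — distort with
a known surface, correct with the same surface, recover the undistorted
feature vectors to 1e−6 — not by datasheet fidelity.

The alternative correction mode appends the raw temperature and humidity
readings as two extra features (87 or 12 in total) before scaling.

## Classifiers and cross-validation

Logistic regression, random forest, gradient-boosted trees, SVM and MLP
delegate to their established implementations (`stats::glm`,
`randomForest`, `xgboost`, `e1071`, `nnet`); hyperparameters are fixed,
documented defaults rather than searched. The extreme learning machine is
implemented natively: seeded uniform random input weights, sigmoid hidden
layer, and output weights by class-weighted ridge least squares on ±1
targets. Its confidence is the logistic of the absolute margin, so
infinite ridge shrinks every confidence to 0.5. All models receive
balanced class weights `n_total / (n_classes · n_c)`.

Three CV schemes are provided. Stratified 10-fold mixes temporally close
samples across the split; leave-5-day-out holds out *contiguous* blocks of
five calendar days (randomising the blocks would destroy the temporal
confound the scheme exists to expose); the 24-hour-group scheme assigns
whole days to folds with greedy label balancing. Repeated runs with
derived seeds quantify initialisation variance; 25 repeats is the
conventional default, though the bundled analyses use fewer for speed.

# The image side and fusion

Detections are filtered at confidence 0.8 (the threshold at which a
precision-oriented deployment operates), merged by greedy same-class NMS at
IoU 0.5 (a standard default; the exhaustive-suppression oracle in the test
suite pins the semantics), and reduced to an image label by the any-ripe
rule. The confidence of a *negative* (unripe) image label is not defined
by the original decision rule; we use
`max(1 − best filtered-out ripe confidence, best surviving unripe confidence)`,
which is monotone in the evidence and configurable. Night status comes
from metadata, never pixel analysis.

Maximum-confidence fusion lets the more confident modality decide, with
ties going to odour, and falls back to odour when the image is missing.
This missing-image policy is what produces accuracy above the image-only
all-samples baseline: an all-weather system must answer at night, and only
the odour modality can. Majority voting needs at least three voters
(typically one image and two odour models); unavailable voters are
dropped, a sub-3 remainder falls back to maximum confidence, and an even
split is decided by the highest-confidence voter.

Agreement analysis restricts to samples where the image modality produced
a prediction *and* both modalities output the same label. With error
processes that are even approximately conditionally independent, the
agreement subset is substantially more accurate than either modality — the
mechanism that makes agreement a usable pseudolabel selector.

# The synthetic generator

The generator is the package's study population, and its defaults are the
study conditions; they are not tuned per analysis.

* **Response model.** First-order exponential approach to a plateau
  proportional to `amplitude(class, sensor) · (VH/7)²`, with separate rise
  (8 s) and decay (15 s) time constants — the standard MOX approximation,
  producing the characteristic response-curve shapes. Per-sensor baselines
  0.8–1.0 V and 7 V-level amplitudes of roughly 1.0–1.5 V (ripe) vs 35 %
  lower (unripe) keep the divider output safely inside (0, 5) V.
* **Noise structure.** Gaussian measurement noise (0.02 V), plus a
  per-day, per-sensor relative amplitude effect (s.d. 0.15) shared by all
  samples of a day — the day-correlated noise that makes stratified CV
  optimistic. The plant class alternates every 3 days over a 25-day
  campaign, as when single plants are swapped in and out of a measurement
  tent, so the label itself is temporally blocked.
* **Environment.** Daily sinusoidal cycles (20 ± 5 °C, 65 ∓ 12 % RH,
  warmest at 15:00) recorded as trace channels and imprinted on sensors
  2–5 through the same RS/R0 surfaces the corrector uses — distortion is
  exactly invertible by construction, which is what the recovery tests
  exploit.
* **Drift.** Multiplicative scaling, linear in days past an onset day or a
  step at the batch boundary. Real campaigns cannot distinguish slow drift
  from sensor repositioning between batches, so both shapes are exposed;
  the default is off because no quantitative drift magnitude is
  established, and the correction/recovery analyses do not depend on it.
* **Images.** Half the samples are at night (no image); daylight lighting
  is categorical (well-lit 40 %, backlit 40 %, artificial 20 % — backlight
  dominating daylight reflects glasshouse conditions). Each true fruit is
  detected independently with lighting/class-dependent probability and a
  Beta-distributed confidence; backlit ripe fruits have lower detection
  probability (0.35 vs 0.90) and lower mean confidence (0.5 vs 0.8) than
  well-lit ones — config validation enforces that ordering — and poorly
  lit unripe fruits are occasionally mislabelled ripe.

What the generator does **not** emulate: real sensor chemistry and
cross-sensitivities, concentration dependence, wind and plume dynamics,
second-order (environmental) drift, correlated multi-fruit occlusion, or
any pixel-level image phenomenon (the vision model is represented by its
outputs only). Passing tests therefore demonstrate that the *analysis
machinery* behaves correctly under the stated statistical structure, not
that any particular accuracy will be achieved on real acquisitions.

# Numerical and design choices

* Zero-range min-max scaling maps to 0 (not NaN), keeping degenerate
  sensors usable; zero denominators in precision/recall report 0 with a
  flag.
* The deep-model preprocessing order is fixed (split → downsample →
  baseline-subtract → min-max) and regression-tested, since reordering
  changes the result.
* NMS ties (equal confidence) break by input order; fusion ties go to
  odour; even majority splits go to the highest-confidence voter. All
  tie-breaks are deterministic so reports reproduce bit-identically.
* Macro-averaged F1 is reported: with imbalanced classes the macro average
  exposes a collapsed class rather than hiding it.
* Seeds: every stochastic step takes an explicit seed or derives one from
  the master seed via a fixed integer recurrence (kept below 2³¹);
  functions restore the caller's RNG state.
* The interpolation solve scales coordinates by their ranges for
  conditioning; degenerate (collinear) reference sets are rejected.

# Problem sizes in the bundled analyses

The test-suite and acceptance analyses use 25-day campaigns of 60–120
samples with DAQ10 traces, 10 replicates for the CV-scheme comparison, and
n = 5000 for the agreement property — sizes at which every property checked
is comfortably resolved while a full run stays in the tens of seconds. The
random-forest model serves as the reference classifier in the CV-ordering
and ablation analyses because it is the most stable performer across
schemes in this regime; logistic regression with 85 features and ~50
training samples is deliberately kept in the suite as the fragile
contrast.

# Known limitations

* The ELM and the suite wrapper support binary problems; multi-class
  ripeness stages would need a one-vs-rest extension.
* The RS/R0 grids are synthetic stand-ins; users with datasheet values
  should supply them via `reference_surfaces(path = ...)`.
* Sequence models (1D-CNN/LSTM) are out of scope; the segmentation,
  downsampling and scaling stages produce their inputs, and any external
  model can join the fusion stage by emitting prediction records
  (`prediction()`).
* `group_24h` balancing is greedy, not optimal; with very few days the
  folds can be fewer than requested.
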