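---
title: "Flight-track features, wrapper selection, and the two-stage cascade"
author: "flightclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flight-track features, wrapper selection, and the two-stage cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightclass)
```

## The problem and the data model

A stereovision bird-protection rig around a wind turbine tracks flying
objects and must decide — from motion and apparent size alone, at ranges up
to several hundred meters — whether a track is an aeroplane, a protected
big raptor, or a common bird. The cost structure is asymmetric: a missed
raptor (false negative) risks a blade strike, a false alarm merely stops
the turbine. The package therefore treats **recall on the protected class**
as the binding constraint and accuracy as the secondary objective
throughout.

A raw track is a 16 Hz series of paired-camera pixel detections
(`x_top, y_top, x_bottom, y_bottom, size_px`). The pixel series are
denoised, triangulated through a vertical-baseline pinhole model
(depth = focal_px · baseline_m / vertical disparity) and converted to
spherical coordinates: elevation `phi = asin(z/r)`, azimuth
`theta = atan2(y, x)`, range `r`. Working in spherical coordinates confines
the (large, range-dependent) stereo quantisation error to `r`; the angular
coordinates are measured to pixel precision.

Two conventions are fixed package-wide and matter for interpretation:
`phi` is elevation *from the horizontal plane* (not the colatitude), and
azimuth is unwrapped across ±π before any differencing.

### Smoothing

Pixel series are denoised with a supersmoother: running local-linear fits
at three spans (0.05, 0.2, 0.5 of the series length), with the span chosen
per point by smoothed leave-one-out residuals. Local-linear fitting makes
the smoother exact on constant and linear series — important because a
steadily drifting pixel coordinate is the common case — while the
small-span option preserves genuine oscillations (wing beats). The spans
are exposed as configuration; nothing in the pipeline is sensitive to them
at the default noise levels, and smoothing can be disabled
(`spans = NULL`).

## The 78-variable feature scheme

From each track the package computes, over consecutive non-overlapping 2-s
windows (32 samples):

* net angular rates `w_phi`, `w_theta` — (last − first angle) / window
  time span. The divisor is the actual span covered by the 32 samples
  (31/16 s), not the nominal 2 s, so a linearly drifting angle yields its
  exact rate;
* arc path lengths `arc_phi = Σ |Δphi_i| · r_i` and
  `arc_theta = Σ |Δtheta_i| · r_i · cos(phi_i)` — true meters travelled in
  each angular direction. The `cos(phi)` factor converts azimuth increments
  to metric arc length on the local circle of latitude;
* the window's mean range, used to place window quantities in distance
  intervals.

The 78 variables are: two 9-bin percentage histograms of the window rates
(ranges ±0.01 rad/s for `w_phi`, ±0.03 for `w_theta`; out-of-range values
are clipped into the edge bins so every histogram totals 100%), averages
of the six quantities within nine distance intervals (default edges
0–900 m in 100 m steps; window quantities are binned by window mean range,
per-sample `phi` and `size_px` by sample range), and the six sample
variances (n−1 denominator).

Design choices worth stating explicitly:

* **Non-overlapping windows** (stride = window). Overlap would double-count
  flapping cycles and make window counts depend on track length in a less
  interpretable way.
* **Empty distance bins are filled with 0**, not NA — a sentinel would
  break z-scoring, and emptiness itself is informative (aeroplanes are
  never seen at 200 m).
* **Bin edges are configuration.** The interval *count* (nine) is part of
  the feature scheme; the default 0–900 m range covers typical bird
  detection distances plus near aeroplane passes.
* **Normalisation by feature group**: z-score for variances and angular
  averages; `log10(1+x)` then min-max to [0, 1] for the size-derived
  features, whose raw values span orders of magnitude; histograms pass
  through. Statistics are frozen on the training rows; held-out rows may
  fall outside [0, 1] and are deliberately not clipped. A constant training
  column gets σ = 1 with a warning rather than an error, since sparse
  distance bins routinely produce constant-zero columns in small samples.

## Thresholded classification and metrics

All four classifier families (random forest, decision tree, one-hidden-
layer perceptron, SVM with cross-validated probability calibration) are
used through their standard R implementations with library defaults
(RF: 100 trees, unrestricted depth, Gini). The package's contribution is
around them: the decision rule `predict 1 iff P(1|x) ≥ threshold`
(inclusive), the stratified repeated hold-out protocol (75/25, five
repeats, means reported in percent), and the goal-driven threshold choice.
Stratification departs from plain random splitting only to guarantee both
classes in every split at the 1 : 5.5 raptor imbalance; recall with zero
true positives raises an error rather than returning 0, because the
protocol guarantees positives and silence would mask a broken split.

## Feature selection

**Correlation filter.** Pearson correlation of each feature with the 0/1
class, then top-n masks (ties broken by lower index) evaluated over a grid
of n and thresholds. The scan reports the full table and the row meeting
both stage goals with maximal accuracy (maximal penalised fitness if none
does).

**Wrapper GA.** Binary chromosomes of length 78; population 400; 200
parents by size-5 tournament; single-point crossover; per-gene mutation at
2.5%; offspring-only replacement; 60 generations by default (the method is
typically run for 50–70). The fitness uses modified scores
`A = 100·acc − th_a`, `R = 100·rec − th_r`, each contributing linearly when
non-negative and `−1.3·|v|^{3/2}` when negative. The exponent is read as
3/2 and kept as a configuration knob. Properties the tests pin down:
fitness is exactly 0 at the goals, strictly increasing in both scores, and
the penalty dominates the linear branch past |v| = 1.

Choices made where the design was genuinely open:

* **Fitness evaluation inside the GA uses one fixed stratified split per
  run** rather than five repeats: it keeps a 400 × 60 run tractable and
  makes mask fitness deterministic, which also enables caching of repeated
  chromosomes. The reported best mask should then be confirmed with the
  full five-repeat protocol.
* **Mutation is per-gene** (the conventional reading of a "2.5% chance
  mutation" in GA libraries), not per-chromosome.
* **No elitism in the population** — only offspring survive — but the
  best-ever chromosome is tracked outside it and returned, so the reported
  best-so-far series is non-decreasing by construction.
* **All-zero chromosomes get a −10⁶ sentinel** instead of an error, so a
  catastrophic mutation cannot abort a run.

## The cascade

Stage 1 (aeroplane = 0 / bird = 1, default threshold 0.4) routes predicted
birds to stage 2 (other bird = 0 / big raptor = 1, default threshold
0.125). Each stage owns its mask, normalisation and threshold; stage 2 is
trained and evaluated on true birds (the "oracle" convention), which makes
its metrics comparable across stage-1 variants; end-to-end behaviour is
available through `cascade_predict()` / `evaluate_cascade()`, whose
three-class confusion composes the two stage decisions exactly.

## The synthetic data generator

Real survey data from operating wind farms are not publicly deposited, so
the package ships a simulator that emulates the *statistical structure the
method relies on*, with three motion archetypes integrated at 16 Hz:

| class | path | speed (m/s) | distance (m) | size scale |
|---|---|---|---|---|
| aeroplane | straight, level | 50–200 | 800–3000 | 30 m |
| big raptor | soaring circles (radius 20–50 m) + slow thermal drift | 10–20 | 100–600 | 2 m |
| other bird | straight + 3 Hz, 0.3 m vertical flap oscillation | 8–15 | 50–400 | 0.45 m |

Apparent size is `round(size_k · (wingspan / r)²)` clipped at 1 px
(size_k = 10⁶, chosen to give plausible pixel counts: tens of pixels for a
raptor at 300 m, hundreds for an aeroplane). Range quantisation follows the
stereo disparity mechanism: `r` is recovered from integer-rounded disparity
with f·B = 4000 m·px, so the error grows with r² and distant aeroplanes
land on a coarse range lattice — the same effect that makes far large
objects hard to localise in real rigs. Gaussian angular noise (sd
2·10⁻⁴ rad) stands in for pixel jitter. Altitude ranges, wingspans and the
noise constants are the package's own engineering choices; they are not
estimates of any real survey's distributions, and results on synthetic
data should never be quoted as reproductions of field performance.

A `separability` control mixes each class archetype with a shared neutral
archetype: at 1 the full class structure is present, at 0 every class is
drawn from the same distribution, giving an exact null for permutation-
style checks.

**What the simulator does not emulate:** multi-object association errors,
weather and lighting, partial occlusions, heterogeneous species within the
"other bird" class, camera vibration, and the heavy-tailed label noise of
expert annotation. Passing tests on synthetic data therefore demonstrate
the *machinery* (features, selection, tuning, cascade) under the assumed
data model — not field-grade performance. The clean archetype separation
makes the synthetic classification tasks easier than the real ones: tuned
random forests typically reach near-perfect stage scores at separability
1, comfortably above the stage goals of 95/97 and 75/90 percent.

## Problem sizes and numerical choices

The test-suite and the acceptance script use a 1000-track simulation
(class proportions 3536 : 7423 : 1325 scaled down, ≈ 288/604/108), five
hold-out repeats per grid point, an 11-point stage-1 threshold grid
(0, 0.1, …, 1.0) and a 20-point stage-2 grid (0.025–0.5 step 0.025, finer
because recall on the 13% raptor minority is much more threshold-
sensitive). Planted-matrix benchmarks (500 × 78, five informative columns
at three-σ effect) verify that both the correlation filter and the GA
machinery recover known informative features; the GA benchmark scores
chromosomes by planted-gene count directly, isolating the evolutionary
machinery from classifier noise. Seeds are explicit arguments everywhere
randomness exists; fixed seeds give bit-identical simulations, splits and
GA runs.

Degenerate inputs are handled deliberately: tracks shorter than one window
are errors (not silently padded); zero/negative disparity raises at
triangulation; the zero vector has no spherical representation; constant
features correlate 0 by convention with a warning; empty masks are errors
except inside the GA, where the sentinel applies.

## Known limitations

* The stereo model is a calibrated-free vertical pinhole; real rigs need
  the full calibration chain, and `raw_to_trajectory()` should be treated
  as a reference implementation of the geometry, not of a production
  localiser.
* Stage-2 "cascade-input" evaluation (scoring stage 2 on stage-1
  survivors rather than true birds) is available only through
  `evaluate_cascade()`'s composed table, not as a separate tuning mode.
* The GA's single-split fitness can overfit the split for very small
  datasets; use the five-repeat protocol on the returned mask before
  drawing conclusions.
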