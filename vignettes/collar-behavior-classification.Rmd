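---
title: "Methods: collar-based cattle behavior classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collar-based cattle behavior classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(grazeclass)
```

## The analysis problem

GPS collars with integrated triaxial accelerometers record, every 5
minutes, a position fix (latitude/longitude, altitude, fix-quality fields)
and three per-interval activity counts (x, y, z channels). Given a few days
of such records plus ground-truth behavior transcriptions from focal
observation, the task is to classify each 5-min instance into cattle
behaviors at several granularities: active vs static, general foraging
(grazing / resting / walking), fine foraging (grazing / resting /
ruminating), posture (standing / lying), and behavior-by-posture.

This vignette documents the modeling choices behind each stage, the
parameters that matter, and what the synthetic-data tests do and do not
demonstrate.

## Pre-processing and movement metrics

Positions are projected to UTM zone 12N (WGS84) before any distance
arithmetic; the transverse-Mercator series implemented in
`project_to_utm()` is accurate to well under a millimeter at paddock scale,
and the unit tests cross-check it against an independent geodesic
computation (`geosphere`). At sub-kilometer step lengths, planar Euclidean
distance on the projected plane agrees with great-circle distance to
better than 0.5%, so all step metrics use the planar metric.

Fix cleaning applies four rules in a fixed order — satellite count,
altitude window, minimum spacing, paddock buffer — and reports the first
failure. Decisions worth recording:

* **Buffer direction.** The 10 m fence buffer is inward (erosion): the
  point of the rule is to drop fence-adjacent fixes whose ~10 m positional
  error could place them in the wrong paddock, so only well-interior
  positions survive. For point queries, erosion is implemented exactly as
  "inside the polygon and at least `buffer_m` from its boundary".
* **Minimum duration.** "At least 5 minutes between records" is enforced
  against the previous *kept* fix of the same animal, which makes the
  filter sequential but idempotent — cleaning the kept set again removes
  nothing, and the tests assert this exactly.
* **Time zones.** Timestamps are stored in UTC; local time is a fixed
  UTC−6 display offset (no daylight-saving logic), since the field
  convention for these deployments is a fixed offset.

Per-step metrics follow the usual movement-ecology conventions: bearing is
the two-argument arctangent of (Δnorthing, Δeasting), i.e. degrees
counter-clockwise from due east in (−180, 180]; the straightness index is
net displacement over cumulative path length, computed here cumulatively
from the start of each animal-day track (the windowing of this statistic is
genuinely ambiguous in field practice — per day, per bout, rolling — so the
per-day-cumulative default is one defensible reading, and the low-level
`straightness_index()` accepts any point sequence). The first fix of a
track gets distance = speed = 0 and straightness 1 so the feature matrix
stays dense and aligned one-to-one with fixes.

## Accelerometer features

The activity channels are opaque counts: the collars' documentation does
not standardize a range, and published descriptions of the axis anatomy
conflict, so the package never assigns anatomical meaning to x, y, z.

The dynamic-body-acceleration statistics need a static/dynamic split. For
per-second waveform data one subtracts a multi-second running mean; for
5-min count data there is no established convention, so the package uses
the same construction at the fix scale: a centered running mean over an
odd window (default 3 fixes = 15 min), shrinking symmetrically at the track
edges. ODBA and VEDBA are then the L1 and L2 norms of the residuals, which
preserves the defining inequality ODBA ≥ VEDBA row-wise. The window is a
tunable compromise: wider windows treat slow activity drifts as "dynamic";
window 1 degenerates to all-zero dynamics.

Pitch and roll are `atan(x / sqrt(y² + z²))` and `atan(y / sqrt(x² + z²))`
in degrees, with the one-sided limit (±90°) when the denominator vanishes;
an all-zero sample has no orientation and errors at the low level (the
table-level builder substitutes 0° so rare all-zero static samples do not
break model fitting).

Energy expenditure over an observed bout is the cumulative Actindex across
the fixes in the half-open interval [start, end) — additive over disjoint
bouts. As a *per-fix model feature*, bout boundaries are unknown at
prediction time, so the `energy` column is the trailing-window Actindex sum
(same window as the dynamic split); the bout-level function remains
available for ethogram summaries.

The six combined products {distance, speed} × {Actindex, ODBA, VEDBA} are
the default cross-sensor features; the pairing is configurable because no
canonical set exists.

## Labels

Transcriptions arrive as behavior bouts. Two rules turn them into per-fix
labels:

1. **3-min bout rule.** An interruption shorter than 3 min belongs to the
   preceding behavior: `merge_short_bouts()` absorbs sub-threshold bouts
   into their predecessor and coalesces the resulting same-behavior
   neighbors, conserving covered time exactly. A short first bout of an
   observation block has no predecessor and is kept.
2. **Window-majority alignment.** A fix summarizes the 5 minutes ending at
   its timestamp, so its label is the behavior occupying the largest share
   of that window, with ties to the earlier-starting behavior (the same
   "belongs to the previous behavior" convention). An instant-based
   alternative (`method = "instant"`) exists for sensitivity checks.
   Fixes overlapping no transcription are dropped and counted rather than
   interpolated.

Grooming and nursing are static when prolonged (≥ 3 min) and `OTHER`
otherwise; `OTHER` is excluded from the modeling tasks. Drinking water is
retained through labeling but excluded from the foraging tasks, and the
general-foraging task folds ruminating into resting, mirroring how the
three-class GR/RE/W and GR/RE/RU task definitions are conventionally
formed. The behavior-by-posture task uses {GR, RE_LD, RE_SU, RU_LD,
RU_SU}; walking and drinking are dropped there as in the fine task.

## The synthetic herd-day generator

The generator is a first-class, tested component, not a fixture. It
emulates:

* **Bout structure**: a semi-Markov process — behaviors alternate according
  to a transition-weight matrix (zero diagonal), bout durations are gamma
  with per-behavior mean and shape, left-truncated at the 3-min bout
  convention.
* **Movement**: a correlated random walk. Step length is (drawn speed) ×
  (interval); heading increments are normal with per-behavior spread, so
  walking is directed (sd 0.4 rad) and grazing confined (sd 1.2 rad);
  static behaviors move only through GPS error. Reported positions add
  isotropic N(0, 10 m) jitter, matching the collars' nominal accuracy.
* **Activity counts**: truncated rounded normals per behavior and axis
  (counts are non-negative integers). Lying postures damp the count means
  by a factor 0.7: a lying collar swings less. The absolute count scale is
  arbitrary and documented as such.
* **Fix-quality defects**: per-fix, mutually exclusive corruption —
  too few satellites, altitude outside the site band, or a position outside
  the paddock — at configurable rates (default 2% each). Clean positions
  are constrained to the interior beyond the fence buffer, so the cleaning
  rules reject *exactly* the injected defects; the tests assert this
  correspondence fix-by-fix.

**Calibration.** For row weights proportional to a share vector q, the
embedded chain's stationary distribution is π_i ∝ q_i(1 − q_i); with mean
bout durations m_i, long-run time shares are π_i m_i (renormalized).
Setting q to the target shares p and m_i ∝ 1/(1 − p_i) therefore makes the
time shares equal p exactly; the 3-min truncation inflates realized
durations, so the raw gamma means are solved numerically so that the
*truncated* means satisfy the proportionality. The default targets are the
reference distribution in `calibration_class_counts()` (1,280 instances:
535 GR, 258 RE, 390 RU, 83 W, 14 DW), and a property test checks the
empirical shares at 5,000 fixes to within ±3 percentage points.

**Emission attribution.** Each fix's behavior, speed and counts follow the
majority behavior of its 5-min window — collar channels aggregate over the
interval, so emissions should reflect the dominant behavior of the window,
not the instantaneous one. This also makes the window-majority labeler an
exact inverse of the generator away from degenerate ties, which is what a
labeling-correctness test needs.

**Scale.** The default campaign is 3 animals × 3 days × three observation
windows (07:00–11:00, 12:00–16:00, 17:00–20:00 local), i.e. 11 h/day at
5-min fixes → ~1,190 raw fixes, matching the scale of a three-day
focal-follow study. Bout-duration baseline is 12 min (scaled per behavior
by 1/(1 − p_i)); real grazing bouts are often longer, but shorter bouts
give more transitions per campaign and hence stronger tests of the bout
machinery at this data size.

**What passing tests do not show.** The generator's emissions are
conditionally independent given behavior, with Gaussian cores and a
perfectly known ground truth. Real collar data have autocorrelated noise,
drifting baselines, transcription error, and behavior-dependent GPS
failure, none of which are simulated. Consequently the near-ceiling
accuracies on the well-separated scenario validate the *pipeline* (no
leakage, labels and features correctly joined, models wired correctly) and
the qualitative patterns (separation knob monotonicity, minority-class
collapse), not field-data performance, which is far lower in published
deployments.

## Classifiers and evaluation

Six families cover the usual spectrum: perceptron, multinomial logistic,
RBF-SVM (C = 1), k-NN (k = 5), random forest (500 trees), and
gradient-boosted trees with the tuned defaults (200 rounds, eta 0.06,
max depth 4, colsample_bytree and min_child_weight 0.5, subsample 0.8).
The margin/distance families are fitted on train-set z-scored features
(scaling fitted on the training part only); tree families use raw
features. The perceptron is implemented in-package (sequential
mistake-driven updates, 1,000 max epochs with early stopping on a clean
pass, softmax over decision values for probabilities) since no installed
package provides a plain perceptron; all other families delegate to the
established implementations behind a single `train_model()` surface.
Every fit is deterministic given the model-spec seed; for the SVM, class
predictions use the (deterministic) decision boundary rather than the
internally cross-validated probability calibration.

Partitioning is class-stratified by default: RTS allocates per-class train
quotas by largest remainder (train size exactly round(0.7 n)); CV assigns
each class round-robin with a carried pointer, so fold sizes are balanced
within 1 both globally and per class. A class smaller than k under
stratified CV is a named error rather than a silent merge. Stratification
is a deliberate default even though random splitting of temporally
adjacent fixes can leak autocorrelation across folds; a grouped-by-animal
protocol would be the stricter design but reduces a 3-animal campaign to
3 folds, so it is left to the user.

CV reports pool the held-out predictions of all folds into a single
confusion matrix (each instance predicted exactly once), with per-fold
reports retained; pooling is the convention that yields a single per-class
number per run. Metrics are one-vs-rest precision, recall and F1 in
percent, with precision 0 for never-predicted classes and F1 = 0 when
precision + recall = 0; all identities (accuracy = trace/total,
F1 harmonic mean) are asserted against brute-force recounts in the tests.
Display rounding is left to `print()`; stored values are full precision.

Partial dependence is the standard estimator computed directly: a grid of
50 equally spaced quantiles between the 1st and 99th percentiles, the
feature forced to each grid value over the whole instance set, predicted
class probabilities averaged. Note that partial dependence answers "does
the *model* use this feature": with many redundant intensity features a
boosted-tree model can achieve the same fit without ever splitting on
speed, giving a flat speed curve; on the compact selected set
(x, y, z, Actindex, distance, speed) the forest's active-class speed curve
rises monotonically, which is the pattern the acceptance checks assert.

## Feature selection

Stage one ranks features by mean Gini impurity decrease from a
500-tree forest, normalized to sum 1, ties broken lexicographically so the
ranking is total. Stage two is a greedy redundancy filter in rank order: a
feature is kept iff its absolute Pearson correlation with every kept
feature is below r_max = 0.9. The threshold, correlation type and tie
policy are configurable since none is canonical; constants are excluded
with a warning (undefined correlation). Lowering r_max can only shrink the
selection, and the selected set depends only on the ranking, not on column
order — both properties are tested. The filter prunes feature–feature
redundancy (its stated purpose) rather than thresholding feature–target
correlation, which the surrounding description of this two-stage recipe
sometimes conflates.

## Numerical and interface choices

* Degenerate inputs error early with named messages: empty training
  classes, even dynamic-component windows, overlapping events, unsorted
  fixes, zero-length paths, identical bearing endpoints, all-zero
  orientation samples.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; campaign-level simulation derives independent child
  streams per animal/day/window, all below 2³¹.
* Problem sizes in the test suite: toy sets of 100–300 rows for exact
  oracles; campaigns of 1 animal-day (~130 instances) for pipeline
  mechanics; the full 3 × 3 campaign (~1,100 instances after cleaning and
  labeling) for the recovery and imbalance checks; 25,000 simulated minutes
  for the stationary-share calibration check.
* On-disk formats are plain text: the collar CSV schema, a transcription
  CSV, and GeoJSON for the paddock polygon (projected meters with the CRS
  recorded as a feature property). The exported functions are the
  interface; `scripts/acceptance.R` is the runnable end-to-end entry point.

## Known limitations

* UTM projection is implemented for the general zone formula but validated
  against oracles only at mid-northern latitudes; no southern-hemisphere
  false northing is applied.
* The paddock model is a single polygon; multi-paddock assignment and
  cross-fence reassignment are out of scope.
* The simulator emits per-interval aggregates only — no sub-second
  waveforms, no grooming/nursing events by default, no social interaction.
* Straightness windowing, axis anatomy, and the static/dynamic split for
  count data are field-ambiguous; the package picks documented defaults
  and exposes them as parameters rather than resolving the ambiguity.
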