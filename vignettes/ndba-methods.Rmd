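---
title: "Distance-to-bound analysis: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-to-bound analysis: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery in `ndbar`: the
distance-to-bound model, each stage's assumptions and tunable parameters, what
the synthetic-data generator does and does not emulate, and the numerical and
design decisions that were genuinely open.

## The model

A two-class linear discriminant fitted to multivoxel patterns defines a
hyperplane `w . x + b = 0` through activation space. The distance-to-bound
hypothesis is that the signed geometric distance of a stimulus's pattern from
that boundary indexes the quality of the categorical evidence, so that
distances correlate negatively with reaction times on the corresponding
categorization task. The package measures that correlation per subject
against a group-averaged behavioral vector, tests the group of correlations
against zero, and bounds the attainable correlation by a joint reliability
ceiling.

### Discriminant and distances

`fit_lda()` computes `w` proportional to `Sigma^-1 (mu1 - mu0)` with the
shrinkage covariance

```
Sigma_hat = (1 - lambda) S_pooled + lambda (tr(S_pooled)/p) I .
```

With 100-voxel neighborhoods and ~150 training samples the pooled covariance
is near-singular, so regularization is not optional. The default `lambda` is
the Ledoit–Wolf analytic estimate computed from the class-centered rows;
any fixed value in [0, 1] can be supplied instead. One caveat found while
validating parameter recovery: in a *nearly noise-free* regime where the
within-class scatter is concentrated along the planted discriminant
direction, the analytic estimate shrinks very little and the discriminant
tilts into poorly estimated low-variance directions; the near-noise-free
recovery test therefore uses strong fixed shrinkage. At realistic noise
levels the analytic estimate behaves well.

`signed_distance()` returns `d(x) = (w . x + b) / ||w||` — a true geometric
distance, invariant to rescaling of `(w, b)`. Scaling does not affect any
correlation the package reports; normalizing simply makes distances
comparable across cross-validation folds. When true labels are supplied the
sign is re-expressed as *correct-side* (positive on the stimulus's own side of
the boundary, negative when misclassified), the convention used throughout
the distance-to-bound analysis; an absolute-distance variant can be had by
taking `abs()` of the result, but the correct-side convention is the default
because a misclassified stimulus has, if anything, *worse* evidence than one
at the boundary.

`crossval_distances()` assigns the `stimulus x run x repeat` samples to five
folds stratified by class and run (a 4/5 train–test split), scores each
held-out sample, and averages each stimulus's held-out distances. Every
sample is tested exactly once per rotation; the per-sample distances are kept
(as an attribute) because the reliability analysis splits them.

### Searchlight and voxel selection

`build_neighborhoods()` takes the `k = 100` nearest voxels around every
center (Euclidean metric on grid coordinates, deterministic z–y–x
tie-breaking). `run_searchlight()` scores each neighborhood by pooled
leave-one-run-out accuracy (compiled core; a neighborhood whose fit fails is
recorded as `NaN`, never fatal). Group inference is a per-voxel one-sided
one-sample t-test of subject accuracies against chance with
Benjamini–Hochberg adjustment over all testable voxels (`q_threshold`
default 0.005). `select_top_voxels()` keeps the top 10% of significant voxels
by group-mean accuracy; group-level ranking (rather than per-subject ROIs)
was chosen so all subjects share one feature set, and an empty mask raises a
typed condition so pipelines can skip that dimension rather than crash.

### Behavior: LISAS and the group vector

Per (subject, task, stimulus), `behavior_scores()` aggregates mean/median RT
(correct trials only by default; `rt_basis = "all"` available), proportion
error, and the linearly integrated speed–accuracy score

```
LISAS_j = RT_j + (S_RT / S_PE) * PE_j ,
```

an accuracy-adjusted RT in milliseconds. `S_RT` is the subject's trial-RT SD
in the task. For `S_PE` two readings exist: the SD of the subject's binary
trial errors, `sqrt(PE(1 - PE))`, or the SD over stimuli of the per-stimulus
error proportions. The package defaults to the trial-level reading. The
reason is statistical: with ~6 trials per stimulus and accuracies near 0.9,
the per-stimulus error proportions vary mostly by binomial sampling, so the
per-stimulus SD *is* that sampling noise; dividing by it makes the penalty
term inject roughly `S_RT` worth of noise into every stimulus's score, and
the adjusted RT becomes less reliable than the raw RT it adjusts. The
trial-level denominator is about three times larger at these accuracies,
weighting errors more conservatively while preserving the score's
interpretation. `lisas_params(pe_basis = "per_stimulus")` restores the other
reading.

Per task, scores are averaged across subjects into a single group behavioral
vector (`group_behavior_vector()`), which is then correlated with each
subject's distances. Subjects whose overall accuracy is not above chance on
every task (one-sided exact binomial, alpha 0.05) are excluded from all
analyses beforehand.

One sign convention worth stating: under a distance-to-bound account, hard
(near-boundary) stimuli are both slow and error-prone, so mean RT and
proportion *error* correlate positively across stimuli (equivalently, RT and
accuracy negatively — the premise of any speed–accuracy integration).
`rt_accuracy_coupling()` reports the RT-vs-error correlation and its group
test under that convention.

### Correlation, inference, and the crisscross combination

`correlate_distance_behavior()` computes each subject's Pearson correlation
between fold-averaged correct-side distances and the group vector, restricted
to one task category (the analysis is run per category because the empirical
coupling is category-asymmetric). Group inference is a two-sided one-sample
t-test on the raw correlations (Fisher-z available but off by default, to
keep the reported `mean r` on the familiar scale); the category asymmetry is
a paired t-test on within-subject differences. Degenerate cases are handled
explicitly: zero-variance vectors yield `NA` and are dropped from the group
test; all-equal correlation sets yield `t = +/-Inf, p -> 0` rather than an
error.

For the crisscross (indoor/outdoor) task no single boundary separates the
categories, and the predictor is built from both single-dimension boundaries:
each distance vector is scaled to percentiles, `100 (rank - 0.5) / n` with
mean ranks for ties (robust to ties, invariant to positive affine transforms,
all-equal input maps to 50), and the two are summed — equal weight by
construction, city-block logic over independently represented dimensions.
Percentile scaling is applied across all 32 stimuli before any category
subsetting (the within-category alternative is a one-liner on the subsets).
In the pipeline's 12-cell summary the combination uses the two classifiers'
distances *within each ROI*; the cross-ROI variant (animacy distances from
the animacy ROI plus shape distances from the shape ROI) is what the
acceptance study evaluates, via `crisscross_distance()` directly.

### Reliability and the noise ceiling

Split-half reliability uses the six run-by-repeat units per stimulus (three
runs cannot be split into balanced run-halves): neural reliability splits the
held-out per-sample distances, behavioral reliability recomputes the group
LISAS vector within each half (including half-specific `S_RT/S_PE`), each
averaged over `n_splits = 100` seeded random balanced splits.
Spearman–Brown, `r_full = 2 r / (1 + r)`, corrects to the full data length,
and the joint ceiling is `sqrt(r_full_behavior * r_full_neural)` — the
maximum correlation the two measurements could exhibit given their noise. A
negative product is reported as an explicit undefined flag rather than an
imaginary number, and plots display the ceiling sign-inverted because the
predicted correlations are negative.

### GIST image control

The image-level control asks which stimulus dimensions are recoverable from
low-level image structure. `compute_gist()` intensity-normalizes the image,
filters it with a bank of frequency-domain Gabor filters (Gaussian in log2
spatial frequency around octave-spaced centers 0.25, 0.125, ... cycles/pixel,
sigma 0.5 octaves; one-sided Gaussian in orientation with sigma
`pi/orientations/sqrt(2)`, which tiles orientation with under 5% ripple),
averages the squared analytic-signal magnitude in a 4x4 block grid, and
concatenates to the 512-value descriptor (block-major, then orientation, then
scale). `crossdecode_descriptors()` then trains a discriminant on the
cluster pair matched on the nuisance dimension and tests on the complementary
pair, both directions, z-scoring features by training statistics. On the
synthetic images, shape cross-decodes essentially perfectly and animacy sits
at chance — by construction, mirroring the intended control logic.

## The synthetic-data generator

`generate_patterns()` plants, per informative region, a per-voxel class-mean
shift of `signal_sd` (in units of the run noise SD) along the region's
dimension, plus a per-exemplar offset along the same direction: stimulus
`j`'s true correct-side distance from the dimension-`k` boundary is
`1 + o_jk` boundary units with `o_jk ~ N(0, exemplar_offset_sd)`. Offsets are
constant across runs (they are the stable exemplar-level structure the
analysis targets) and are drawn **per subject**. That last choice is
deliberate and consequential: if exemplar structure were shared across
subjects, the per-subject correlations with the shared group vector would be
correlated across subjects and the group one-sample t-test would be
anti-conservative under the null. Drawing offsets per subject keeps the null
calibrated (measured false-positive rate ~0.05), at a price discussed under
*Limitations*.

`generate_behavior()` draws one trial per stimulus x run x repeat with

```
RT = intercept + slope * m(category) * |d| + N(0, rt_noise),  floor 150 ms
p(correct) = plogis((accuracy_base + m(category) * |d|) / accuracy_link_scale)
```

The per-category multiplier `m` gates the *effective distance* driving both
speed and accuracy, so a category with `m = 0` has flat RTs **and** flat
(baseline, ~0.88) accuracy — if errors stayed distance-coupled, the LISAS
error penalty would silently re-introduce coupling in the "uncoupled"
category and the planted asymmetry would be unrecoverable. The crisscross
task's driving distance is the mean of the two dimensions' absolute
distances (a scaled city-block sum). `accuracy_link_scale = 0` is the
deterministic limit (every response correct), used together with
`slope = 0` as the null configuration for calibration checks.

Default conditions: 8 subjects, 3 runs per task, 2 repeats per run, a
28 x 9 x 8 grid (2016 voxels) with two 150-voxel blocks placed flush against
opposite z-faces of the grid. The flush placement is intentional: a block
floating mid-grid leaves a voxel layer beneath it whose (edge-clipped)
neighborhoods contain *more* block voxels than the block interior's own
neighborhoods, so the top-accuracy voxels land outside the region being
recovered. The effect-size defaults (`rt_slope = -250 ms` per boundary unit,
`rt_noise = 80 ms`, `exemplar_offset_sd = 0.7`) were calibrated, as in any
simulation study, so that the primary planted effect — coupling confined to
the animate category — is recovered with roughly 80–85% power at the default
sample size; the calibration logic is a design property of the generator, not
a fit to any data.

All randomness flows from one root seed via named substreams
(`substream_seed(seed, "patterns", subject)`, ...), so patterns, behavior,
and images can be regenerated independently and bit-identically.

## Monte-Carlo problem sizes

The end-to-end test studies run on reduced problem sizes chosen for
statistical adequacy: parameter recovery, null calibration, noise ceiling,
and crisscross comparisons use a 300-voxel grid fully covered by the two
planted regions (the searchlight stage is exercised separately at full size)
with 100, 200, 100, and 50 replicates respectively; reliability inside
replicates uses 20 splits (split-to-split SD of the mean is ~0.01 there).
The full-size pipeline, including both searchlights and 100-split
reliabilities, runs in a few minutes on one CPU.

## Limitations

- **No shared exemplar structure.** Real observers agree on which exemplars
  are typical, so real data carry stimulus-level structure shared across
  subjects; there, group-averaged behavior can correlate with individual
  distances far above `1/sqrt(n_subjects)`. The generator omits this
  component to keep group inference calibrated, which caps the attainable
  group mean correlation at `1/sqrt(n_subjects)` (~0.35 at n = 8) and caps
  the power of the paired category-difference test near 0.5–0.6 at any
  sample size — the group-vector dilution cancels the t-test's sqrt(n) gain
  exactly. Passing recovery tests therefore demonstrate the pipeline's
  correctness, not the effect sizes real data would show; conversely, strong
  published correlations imply shared structure the generator deliberately
  does not model.
- **No hemodynamics, GLM estimation, spatial autocorrelation, or realistic
  brain geometry**; patterns are beta-like values on a rectangular grid with
  i.i.d. Gaussian noise. Searchlight inferences about smoothness-dependent
  behavior (cluster extent, etc.) are out of scope.
- **Selection and estimation share data.** As in the standard pipeline, the
  ROI is selected and the distances estimated from the same patterns (with
  cross-validation inside each step); the recovery tests quantify the net
  behavior of that combination, not an unbiased decomposition.
- **Stable exemplar offsets make stimuli individually memorizable** across
  runs, which mildly inflates decoding accuracy wherever any stable stimulus
  structure exists. This is a property of real rapid-event designs too
  (same stimuli recur in every run).
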