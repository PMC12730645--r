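---
title: "Capsule-network emotion classification from eye tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsule-network emotion classification from eye tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Eye movements carry affective information without any electrode or camera
pointed at the face: pupil diameter co-varies with arousal, and the
rhythm of fixations and saccades shifts with emotional state. `gazecaps`
classifies emotional state (e.g. low/medium/high arousal) from gaze and
pupil recordings alone. The pipeline is: raw-signal preprocessing,
velocity-threshold (I-VT) event detection, sliding-window moment
statistics, rolling temporal feature doubling, one-way ANOVA feature
screening, and a capsule network with an MLP head trained under a joint
margin + class-weighted cross-entropy loss.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical conventions, and the choices made where the
design was genuinely open.

# Preprocessing

Raw recordings are one row per sample: time (s), horizontal and vertical
gaze position (degrees of visual angle), pupil diameter (mm) and a
tracker confidence in [0, 1]. Three steps run per trial:

1. **Duration screening.** A trial whose missing duration exceeds half of
   the expected experiment length is dropped. "Observed" duration counts
   samples at or above the confidence cutoff; missing exactly half is
   kept (the rule is a strict exceedance).
2. **Confidence cleaning.** Samples with confidence below the cutoff
   (default 0.95) are invalidated in the gaze and pupil channels and
   refilled by linear interpolation between the nearest valid
   neighbours. Leading and trailing invalid runs take the nearest valid
   value, because linear interpolation needs two anchors and
   extrapolation would manufacture trends. The cutoff is applied per
   sample, not per trial: only the per-sample reading is compatible with
   an interpolation step. Series length and the time grid never change.
3. **Median filtering.** A running median (default width 5 samples,
   about 21 ms at 240 Hz — the smallest odd width that removes isolated
   one- to two-sample spikes) is applied independently to gaze x, gaze y
   and pupil. Edges use symmetrically shrinking windows; confidence is
   untouched.

Blinks are treated as confidence dropouts, not as a third event class:
the cleaning step removes and interpolates them, which is exactly what
the downstream statistics expect.

# Event detection and window features

**I-VT.** The angular velocity between consecutive samples is the
forward difference `v_i = sqrt(dx^2 + dy^2) * rate`; velocity `i` is
attributed to the transition from sample `i` to `i + 1`. A velocity at
or below the threshold `V0` (default 45 deg/s) is a fixation sample,
strictly above is a saccade sample. Maximal runs of equal labels become
events; fixation runs shorter than the minimum fixation duration
(default 55 ms) are relabelled saccade and merged with their
neighbours. Events therefore tile the velocity index range exactly, a
property the tests assert.

**Windows.** A 5 s window slides in 1 s steps (both configurable); a
trailing partial window is dropped. For every window, five parameter
families are summarized: pupil diameter (per sample), fixation duration,
saccade duration, saccade mean speed and saccade distance (per event).
Events straddling a window boundary belong to every window they
intersect, with duration, displacement and mean speed recomputed on the
intersection — this preserves per-window event sets without
double-counting full durations. Each family yields mean, kurtosis,
skewness, variance and coefficient of variation: 25 features per window.

Moment conventions (the literature names these statistics without fixing
conventions, so the package fixes them and tests against brute-force
recomputation):

* variance is the population variance;
* kurtosis is Fisher excess kurtosis (0 for fewer than 2 values or zero
  variance);
* skewness is the adjusted Fisher–Pearson form, 0 for fewer than 3
  values;
* CV is `sd / |mean|`, defined as 0 when `|mean| < 1e-12`;
* a family with no events in the window contributes zeros.

**Rolling doubling.** Each feature column is augmented with its trailing
rolling mean over `roll_w` windows (default 5; the length is a project
choice — the source literature never states one). The prefix expands
(window `i < roll_w` averages all available windows), so the feature is
causal and usable online. This doubles the feature dimension and leaves
the window count unchanged: `[1000, 13]` becomes `[1000, 26]`.

**ANOVA screening.** For every raw statistical feature, a one-way ANOVA
F test (via `stats::oneway.test`, equal variances) is run for each
pairwise class contrast; a feature is retained when significant
(`p < 0.05`) in at least `min_contrasts` contrasts (default 1). The
screening is computed on the 25 raw statistics and the retained set is
then doubled — selection before doubling keeps original/rolled pairs
together. No single "at least k significant contrasts" rule reproduces
every published feature-selection table we are aware of; the rule is
therefore configurable rather than hard-coded.

# The capsule network

Let `F` be the input dimension after screening and doubling. The network
is:

* **Primary capsules.** An affine map `S = X W + b` into `m * n` values
  (defaults `m = 16` capsules of dimension `n = 8`), reshaped per
  capsule and squashed. The squash nonlinearity
  `v = (||s||^2 / (1 + ||s||^2)) s / ||s||` compresses norms into
  [0, 1) while preserving direction; the zero vector maps to zero.
  Fully connected capsules replace the convolutional original because
  windowed gaze features have no spatial grid.
* **Prediction vectors.** Every (primary capsule k, class j) pair owns an
  exclusive `n x n` matrix: `u_hat[k->j] = W_kj v_k`.
* **Dynamic routing.** Logits start at zero. Each iteration: couplings
  are the class-axis softmax of the logits; each class capsule is the
  squash of the coupling-weighted sum of its prediction vectors; logits
  grow by the agreement `u_hat . v`. After `R_base = 3` iterations the
  variance of each class capsule's length across the mini-batch sets a
  per-class extra budget `extra_j = round(alpha * Var_j)` (`alpha = 1`;
  `ceiling` optional), and routing continues with a class frozen once
  its extras are spent. The batch variance is the only point at which
  the capsule lengths exist, which resolves the circularity of a
  capsule choosing its own iteration count. Note that squashed lengths
  lie in [0, 1), so their variance is at most 0.25 and nearest-integer
  rounding usually yields zero extras; the behaviour is preserved as
  specified, with the rounding switch provided. With `alpha = 0` the
  mechanism is exactly inert — a property asserted bit-for-bit in the
  tests.
* **MLP head.** The three 8-D class capsules are flattened into a 24-D
  vector and passed through 24 → 128 → 256 → C with BatchNorm
  (momentum 0.05), LeakyReLU (slope 0.2) and dropout 0.5 after each
  hidden layer. Eval mode uses running statistics and is deterministic;
  train mode refuses batches of one sample (batch statistics would be
  degenerate).

# The dual loss

Two losses backpropagate jointly through the shared capsule parameters:

* **Margin loss** on capsule lengths, read before the MLP:
  `sum_j [ y_j max(0, 0.9 - l_j)^2 + 0.5 (1 - y_j) max(0, l_j - 0.1)^2 ]`,
  averaged over the batch. The thresholds push the true class's length
  toward 1 and the others toward 0.
* **Class-weighted cross-entropy** on the MLP logits, with weights
  refreshed once per epoch from the validation confusion matrix:
  `error_j = 1 - recall_j`, `w_j = (error_j + eps) / (mean error + eps)`
  with `eps = 1e-3`, so harder classes weigh more, a perfectly
  classified class keeps a small positive weight, and the all-zero-error
  case is defined. The first epoch uses unit weights; a class absent
  from the validation split keeps its previous weight. The refresh uses
  an inner stratified validation split (10% of the training data, fixed
  per fold) — refreshing from the test fold itself would leak.

The total objective is `margin + lambda * CE` with `lambda = 0.1`.

**Gradients.** Everything is hand-differentiated in double precision.
By default the routing couplings are treated as non-differentiated
control flow: gradients flow through the final aggregation only, as in
common capsule implementations. A `routing_grad = "full"` switch
backpropagates through the unrolled routing iterations (softmax, logit
updates and all); it requires a fixed iteration count (`alpha = 0`),
since the per-class freezing schedule is data-dependent. Finite
differences confirm the full-mode gradients to better than 1e-4
relative error, and the detached mode is exact at one routing iteration,
where couplings are input-independent.

**Optimization.** AdamW (decoupled weight decay 1e-4, learning rate
1e-3, batch size 32) with cosine annealing over the epoch budget
(default 100 epochs; 20 is typical for small cross-session protocols).
Features are standardized to zero mean and unit variance using
training-fold statistics before the capsule layer — the affine primary
projection is scale-sensitive. Non-finite losses abort with diagnostics.

# Class balancing and evaluation

SMOTE equalizes training classes to the majority count: each synthetic
sample is `x + u (x_nn - x)` with `u ~ U(0, 1)` and `x_nn` one of the
`k = 5` nearest same-class neighbours. Balancing and standardization are
fit inside training folds only; the tests assert that test rows are
untouched. "Subject-independent" oversampling is read as: the train/test
split respects grouping, and SMOTE runs only inside the training
partition (neighbours may span training subjects) — the only reading
consistent with the leakage concern that motivates it.

Cross-validation is stratified by default, or grouped (subject/session)
so a group never straddles the divide; accuracy is reported per fold
with mean and standard deviation, plus the confusion matrix aggregated
over folds (row-normalized form sums to 1 per row).

# The synthetic gaze generator

No public eye-tracking dataset ships with the package; instead
`generate_gaze_dataset()` emulates class-dependent gaze statistics so
the full pipeline is testable end to end:

* trials alternate fixation plateaus and constant-velocity saccade
  ramps; ground-truth segments are returned with the signal;
* fixation durations are Gaussian per class (defaults 250/400/600 ms,
  sd 50 ms), truncated below at 70 ms so every planted fixation survives
  the 55 ms minimum-duration rule;
* positional jitter is Gaussian (sd 0.01 deg) with a per-axis clamp
  that keeps intra-fixation velocities strictly below the I-VT
  threshold, so event recovery is exact by construction;
* saccade amplitudes are Gaussian per class (defaults 4/5/6 deg, sd
  1.5) at constant peak speeds 250/300/350 deg/s, all clearly above the
  threshold;
* pupil diameter is class mean (defaults 3.0/3.5/4.0 mm) plus a
  per-subject baseline offset (sd 0.15 mm between subjects) plus
  per-sample Gaussian noise (sd 0.2 mm);
* blinks (class rates 10/12/15 per minute) and random dropouts (2% of
  samples) carry sub-threshold confidence; blink pupil values are a
  sentinel that the cleaning step removes.

The default conditions — 10 subjects, 4 trials per subject per class,
3 classes, 60 s at 240 Hz — are the package's reference benchmark: the
full pipeline with ANOVA screening, rolling doubling, SMOTE and a
30-epoch fit reaches well above 90% five-fold mean accuracy against a
33.3% chance level (the tests assert the 90% bound).

What the generator does **not** emulate: main-sequence saccade dynamics
(amplitude–velocity coupling), microsaccades and drift, smooth pursuit,
screen-coordinate optics, and any correlation structure between pupil
and gaze kinematics beyond the class conditioning. Passing the benchmark
therefore demonstrates that the implementation learns the statistical
structure it is pointed at — not that these effect sizes are attainable
on real recordings, where class differences are far subtler and
between-subject variability dominates.

# Numerical choices and degenerate inputs

* Squash gradients at the origin are 0 (the map is quadratic there);
  norms below 1e-12 short-circuit.
* Routing logits initialize to 0, so first-iteration couplings are
  exactly uniform (`1/C`); logits reset between forward passes.
* The duration screen keeps a trial missing exactly half.
* A cleaning step with zero valid samples raises an unrecoverable-trial
  error; a single valid sample extends everywhere.
* ANOVA on a feature constant within a contrast is undefined and counts
  as not significant; `alpha = 0` retains nothing.
* Windows with no saccades produce defined zeros for all 15
  saccade-family features.
* SMOTE on a singleton class falls back to duplication with a warning.
* Batches are assembled so no training batch has fewer than 2 samples.

# Problem sizes

The shipped tests and the acceptance script run the reference benchmark
at its native size (120 trials of 60 s at 240 Hz, 6,720 windows, 5-fold
CV at 30 epochs) and keep unit tests on small synthetic fixtures built
in code; the whole suite completes in a few minutes on one core.

# Known limitations

* The adaptive iteration count depends on the mini-batch composition;
  at prediction time extras are computed per forward chunk, which can
  in principle make single-sample and batched predictions differ. With
  the default `alpha = 1` and nearest rounding the extras are almost
  always zero (length variance is bounded by 0.25), so this is a
  theoretical rather than practical concern.
* Routing gradients are detached by default; the full-gradient mode
  exists but only for fixed iteration counts.
* The CE class-weight refresh requires a validation split; with
  `val_fraction = 0` weights stay at 1.
* R-level loops over capsule pairs bound throughput; the defaults
  (16 x 8 capsules, 3 classes) train comfortably on one core, but much
  larger capsule layers would warrant a compiled backend.
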