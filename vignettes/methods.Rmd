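---
title: "Methods: offline fixed-K re-identification and pose annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: offline fixed-K re-identification and pose annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reidkit)
```

## The re-identification model

`reidkit` targets recordings in which the number of unique individuals
`K` is known in advance and processing is offline. Each person detection
in frame `t` carries an appearance embedding `x ∈ R^d` produced by some
perception backend (a re-identification network in practice; the
synthetic backend here). The modelling assumption is that embeddings of
one person scatter around a person-specific centroid, and that distinct
people have distinct centroids: `x = c_k + ε`, with `ε` isotropic. Under
that assumption, clustering *all* embeddings of a session into exactly
`K` groups recovers identities without any labelled examples, and is
robust to occlusion gaps of any length — a detection after re-entry is
assigned by appearance alone, not by motion continuity.

Clustering is k-means with fixed `K`: k-means++ seeding (first centroid
uniform over points, each next one drawn with probability proportional
to squared distance to the nearest chosen centroid), Lloyd iterations,
and the best of `n_restarts = 10` runs by inertia. Identity assignment
then proceeds frame by frame under the *per-frame uniqueness*
constraint — two people in one frame cannot be the same person:

* **flag mode** (the default): each detection goes to its nearest
  centroid independently; when two or more detections of a frame land
  on the same cluster, *all* of them are marked mistaken and receive the
  reserved label `UNKNOWN`. The symmetric treatment is deliberate:
  without a principled tie-break there is no reason to trust either
  colliding detection, and downstream analytics simply drop `UNKNOWN`.
* **optimal mode**: the collision is resolved by the minimum-total-
  squared-distance one-to-one assignment (Hungarian algorithm). When a
  frame holds more detections than clusters, the `n − K` detections not
  matched by the minimum-cost solution are marked mistaken.

A frame whose detections all have distinct nearest centroids is already
optimally assigned, so both modes agree there; the modes differ only on
collision frames. Semantic labels (`"Therapist"`, `"Patient"`, ...) come
from a researcher-supplied injective mapping over clusters.

### Embedding normalization

Embeddings are L2-normalized before clustering by default
(`normalize = TRUE` in `run_reid()`). Appearance-embedding similarity is
conventionally cosine-like, and normalization makes the
separation-to-noise ratio scale-free, so it is the sensible default; a
flag disables it for backends whose embedding norms are meaningful.

### Numerical choices

* Convergence uses the relative rule common to reference k-means
  implementations: stop when the summed squared centroid shift falls
  below `tol × mean per-feature variance` of the data, with
  `tol = 1e-4` and at most 300 iterations.
* A cluster left empty after an assignment step is re-seeded at the
  point farthest from its assigned centroid — deterministic given the
  seed, and it preserves exactly `K` clusters as the model requires.
* Nearest-centroid ties break toward the lower cluster index
  (`ties.method = "first"`); exact ties occur only on degenerate inputs
  such as duplicated points.
* The Hungarian solver is the shortest-augmenting-path formulation with
  potentials, valid for rectangular cost matrices (`rows ≤ columns`),
  and rejects non-finite costs.
* All randomness is seeded; `fit_kmeans()`, the generators and the
  evaluation samplers are reproducible bit-for-bit from their seed.

## The synthetic study conditions

`simulate_session()` emulates the recording setting the pipeline is
built for, and its defaults are the package's declared study
conditions:

* `K` identities with centroids drawn in `R^d` (`d = 512`, matching the
  typical output of person re-identification networks) and rescaled so
  the minimum pairwise distance equals `centroid_separation`
  (default 10). Embedding noise is isotropic Gaussian with
  `noise_sigma = 1`, making `centroid_separation / noise_sigma` the
  single difficulty knob.
* Presence follows an independent 2-state Markov chain per identity:
  absent→present with `enter_prob = 0.2`, present→absent with
  `exit_prob = 0.05`, initial state present. Mean visible spells last
  `1/exit_prob = 20` frames and occlusion gaps `1/enter_prob = 5`
  frames, and the long-run present fraction is
  `enter_prob / (enter_prob + exit_prob) = 0.8`. These two rates are
  exposed in the config because occlusion statistics of real sessions
  vary widely; the defaults produce sustained occlusions and re-entries
  without emptying the scene.
* An optional *confusable pair* places two centroids exactly
  `reduced_separation` apart — the similar-clothing failure mode, under
  which misassignments concentrate on that pair's confusion cells while
  the remaining identities stay accurate.
* Bounding-box centres follow a reflected Gaussian random walk inside
  the image; trajectories are plausible for centroid-track plots but
  carry no biomechanics.

What the generator does **not** emulate: detector misses and false
positives, embedding drift with pose or lighting, anisotropic or
heavy-tailed appearance noise, and correlated presence (people leaving
together). Passing tests on this generator therefore demonstrate the
correctness and the qualitative behaviour of the algorithms — perfect
recovery when separation dominates noise, graceful and monotone
degradation as appearance overlaps, failure concentrated on confusable
pairs — not a performance guarantee on any particular real dataset.

## Skeletons and pose classification

Skeletons use the standard 25-keypoint body layout (`Nose = 0`,
`Neck = 1`, `MidHip = 8`; `body25_keypoints()` gives the full order) in
full-frame pixel coordinates, with missing keypoints encoded as
confidence 0. The synthetic skeleton generator encodes posture
geometrically: standing draws a hip–knee–ankle angle in [165°, 180°]
with near-vertical thighs (MidHip-to-ankle vertical extent about twice
the torso length), sitting draws a knee angle in [80°, 100°] with
horizontal thighs (extent about one torso length). With zero noise a
130° knee-angle threshold separates the classes perfectly, which pins
down the generator's separability; angle noise (default 5°), keypoint
pixel noise and independent keypoint dropout then blur it.

Features fed to the classifier are translation- and scale-invariant:
all 25 keypoints centered on MidHip and divided by the torso
(Neck–MidHip) length, five joint angles in degrees (both knees, both
hips, trunk inclination from vertical), and 25 missingness indicator
bits. Skeletons missing either anchor are skipped (never imputed —
imputation would inject pose information the estimator did not
observe); at prediction time they receive the reserved label
`UNSCORED`. The classifier is a gradient-boosted tree ensemble with
default hyperparameters (100 rounds, depth 6, learning rate 0.3,
logistic objective, single thread) — no tuning, by design. The feature
schema is versioned so alternative representations can be swapped
without silently mixing models.

Evaluation is leave-one-session-out group-k-fold: one fold per session,
every session held out exactly once, so no session contributes to both
training and testing. Summary precision/recall/F1 weight each fold by
its number of scored test frames (the natural reading of
frame-weighted averaging); the across-fold mean and standard deviation
are reported alongside. A held-out session containing a single class
yields undefined metrics for the absent class, reported as missing
rather than zero.

## Behavioural analytics

* **Centroid tracks**: `(x_min + width/2, y_min + height/2)` per
  detection, one series per semantic label, gaps preserved (no
  interpolation), `UNKNOWN` dropped.
* **Pose event intervals**: maximal constant-label runs;
  `UNSCORED` frames and frame gaps break runs. `min_duration` merges
  runs shorter than the threshold into the neighbouring longer run
  (preceding run on ties), then fuses equal neighbours, repeating until
  stable — the default of 1 applies no smoothing, since the underlying
  event structure should be a researcher's choice, not a hidden filter.
* **Joint variance**: the movement-variability index of one identity in
  one session is `Var(X) + Var(Y)` of a chosen joint (Neck by default)
  over qualifying frames, using the sample (n−1) variance. Frames
  where the joint is missing are excluded and counted; typically the
  qualifying filter keeps only frames classified as sitting, so
  postural changes do not masquerade as head movement.
* **Cross-session trend**: ordinary least squares of the per-session
  variance on the integer session index with a two-sided t-test on the
  slope (method-tagged `"ols_t"` so a rank-based alternative can be
  added). An exact zero-residual fit is reported with `p_value = 0` and
  a degeneracy flag. OLS is a deliberate, transparent stand-in: the
  trend of interest is a monotone decrease, and the calibration of this
  test (size ≈ 5% under a constant-jitter null, high power under
  linearly decaying jitter) is itself checked in the test suite.

## Scoring conventions

Re-identification accuracy is frame-level: a frame counts correct only
when *every* detection in it carries the right label, frames with zero
detections are excluded from the denominator, and `UNKNOWN` counts as
incorrect. Partial credit at the detection level is reported separately
(`detection_accuracy`), and the confusion matrix is counted per
detection. Group summaries take the median accuracy across the videos
of each group (midpoint of the two central values for even counts) and
exact sums for count columns. Track audits count distinct track ids in
an external MOT file against the true `K`, reporting the signed
difference — the over-detection index for trackers without a hard
identity limit.

## Centroid recovery at the standard-error scale

On separable scenarios, the fitted centroid of cluster `k` averages
`n_k` noisy embeddings, so each coordinate estimates the true centroid
coordinate with standard error `σ/√n_k`, and the Euclidean error
satisfies `E‖err‖² = d·σ²/n_k`. The recovery check therefore bounds the
Euclidean error by `3·σ·√(d/n_k)` — three standard errors in the
dimension-correct metric. A bound of `3σ/√n_k` on the Euclidean
distance itself would be unattainable for `d > 9` even for the oracle
partition, which is why the per-coordinate formulation is the one the
package asserts.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use sizes the package
declares as its synthetic study conditions: 200 random 5×5 matrices for
the assignment-solver oracle; 100 random 10-point instances for the
k-means oracle (exhaustive search over all 511 bipartitions); perfect
recovery on `K ∈ {2..5}`, 2,000-frame, 512-dimensional sessions at
separation 10σ, 5 seeds each, both modes; a 4-identity confusable-pair
session at 1σ; a 5-point separation grid (8, 4, 2, 1, 0.5 at σ = 1)
with 20 seeds per point; 10 sessions × 500 frames for the pose
pipeline; 1,000 null and 100 alternative replicates for the trend
calibration. All quantities reported anywhere are computed by those
runs at run time.

## Known limitations

* `K` must be known and constant within a session; estimating `K` is
  out of scope by design.
* Clustering is appearance-only: no motion model, no temporal
  smoothing. Two people in genuinely identical clothing are
  irreducibly confusable, and the failure is (verifiably) concentrated
  on that pair.
* Flag mode discards all colliding detections rather than adjudicating;
  optimal mode is the built-in alternative.
* The pose task is binary (sitting/standing); additional classes would
  need new labels and a schema bump, not a new mechanism.
* Real-model perception backends are interface stubs by design; the
  synthetic backend is the reference implementation of the contract.
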