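---
title: "Methods: approach-avoidance state analysis for dPAG calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: approach-avoidance state analysis for dPAG calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagstates)
```

## Scope and model

`pagstates` analyzes miniscope calcium recordings of dorsal periaqueductal
gray (dPAG) populations during two defensive assays: the elevated plus maze
(EPM; two open and two closed 30 x 7 cm arms around a 7 x 7 cm center) and a
70 x 26 cm rat-exposure arena in which a tethered rat occupies one end and
the opposite 20% of the arena is a safe zone (a toy-rat session serves as
the no-threat control). Neural data are per-cell dF/F traces at 7.5 Hz;
behavior is keypoint tracking (nose, ears, tailbase, and the rat) at 30
frames/s, a 4:1 ratio that makes block alignment exact.

The package asks one question in several ways: is the animal's position on
an avoidance-approach axis represented in dPAG population activity?
The stages are independent estimators of that representation —
per-cell arm-preference ensembles, population decoding, an encoding GLM,
a cross-assay shared projection (CoCA), and unsupervised state discovery.

## Trace conditioning

Order is fixed: artifact suppression on raw traces, then variance
thresholding, then z-scoring, then alignment to the behavioral clock.

* **Artifact suppression.** PCA across cells; components carrying >= 5% of
  total variance are candidates. The original workflow flagged artifact
  components by eye; as a reproducible surrogate, a candidate is
  auto-flagged when more than 60% of its projected power lies below
  0.01 Hz, which captures session-scale bleaching while sparing behavioral
  tuning (open-arm bouts turn over far faster than 100 s). A manual index
  list always overrides the criterion. The step is optional per session,
  as shared slow artifacts are rare.
* **Variance thresholding.** Cell variances are sorted in decreasing
  order; the reference cell sits at the curve's elbow, computed as the
  maximum perpendicular distance to the chord between the first and last
  points *after normalizing both axes to [0, 1]* (in raw units the
  variance axis dominates and cliff-shaped curves lose their elbow). When
  the farthest point falls below the chord — the signature of a sharp
  cliff — the elbow cell is the previous, high-variance one; when no
  elbow exceeds a 0.05 normalized distance, the highest-variance cell is
  the reference. Cells below 10% of the reference variance are discarded;
  the reference itself never is.
* **z-scoring** uses the session-wide mean and *population* SD (divisor
  n), matching the plain (x - mu)/sigma definition, and is applied exactly
  once: re-z-scoring is refused rather than silently repeated.

## Behavior classification

All detectors run on kinematics smoothed with a 0.33 s centered moving
average (the freeze-duration scale; suppresses tracker jitter). Freezing:
head *and* tailbase speed below 0.25 cm/s for >= 0.33 s. Approach/escape
(rat assay): body speed above 3 cm/s while moving toward/away from the
rat; direction is the sign of the distance-to-rat displacement over a
0.33 s window, held when displacement is under 0.1 cm (near-stationary
frames carry no direction of their own); bouts also require 0.33 s. Rat
movements: raw rat speed above its session 99.5th percentile, keeping only
the first event within any 5.33 s window, each annotated with the movement
angle relative to the mouse (0 degrees = toward the mouse). Head dips have
no printed rule; the configurable surrogate used here is nose beyond the
open-arm boundary while the body centroid is inside an open arm, for
>= 0.2 s.

Two derived per-frame scores:

* **EPM location index** = |x| - |y| on coordinates normalized so open-arm
  ends are x = +/-1 and closed-arm ends y = +/-1.
* **Avoidance/approach score.** Distance-to-safety is the distance from
  the safe wall (rat assay, scaled to [0, 1]) or the geodesic distance
  from the nearest closed-arm end along the arm axes through the center
  (EPM, scaled to [0, 0.9]); the geodesic, not the Euclidean, distance is
  used because retreating from an open arm requires traversing the center.
  Toward-threat frames score +distance-to-safety; away frames score
  -(1 - distance-to-safety); freeze frames are forced to -1 in both
  assays; EPM head-dip frames are multiplied by 1.11 so a dip at the open
  arm's end reaches the maximum of 1. Output is clipped to [-1, 1].

## Ensembles, decoding, encoding

**Categorization** calls a cell open-arm-preferring when each individual
open arm's samples exceed the pooled closed-arm samples (one-sided
Wilcoxon rank-sum, p < 0.05, both arms), and symmetrically for closed. The
test's sidedness is not printed anywhere; one-sided is used because the
hypothesis is directional ("significantly greater"). Per-frame samples are
autocorrelated, which inflates the nominal test level — a documented
caveat shared with the convention this follows; the 40/60 split (first 40%
categorizes, last 60% after a 10 s gap evaluates) exists to keep activity
estimates unbiased. Benjamini-Hochberg correction is available but off by
default (the categorization rule is stated at raw p < 0.05).

The **open-arm preference score** is 2 AUC - 1 from thresholding a single
cell's activity to predict open vs closed occupancy; it is computed by the
rank-sum identity, which equals trapezoidal ROC integration with ties
counted half. The **EPM score** is (A - B)/(A + B) with A the mean
between-type and B the mean within-type absolute activity difference;
A = B = 0 is defined as 0 (no arm information). Peri-event activity uses a
[-5, +5] s onset-aligned window, with activity change = mean over [0, 2.5]
minus mean over [-2.5, 0] s ([-5, -2.5] s pre-window for head dips), and an
optional rule excluding escapes/freezes within 10 s after the other
behavior to limit slow-kernel carryover.

**Decoding** interleaves 60 s train / 60 s test blocks with 10 s gaps (gaps
absorb calcium dynamics across the boundary). Arm type: linear SVM
(C-classification, `e1071`/libsvm), balanced class weights, C = 1 (not
printed; exposed in the call), center frames excluded from train and test
(they carry no arm label, so exclusion on the test side is forced);
significance from 100 refits with shuffled training labels,
p = (1 + #{null >= obs})/(1 + N). Location index: ordinary least squares,
predictions clipped to [-1, 1], Pearson r on test.

The **encoding GLM** is Gaussian-identity least squares per cell on
behavior variables convolved with a log-time raised cosine basis
f_j(x) = (cos(pi x - phi_j) + 1)/2, x = log(t + b + eps),
phi_j = log(b + eps) + (j - 1) pi/2, zero outside phi_j/pi +/- 1. Basis
count and offsets are not printed; the defaults J = 5, b = 0.25 s,
eps = 1e-3 s put the last peak near 4.5 s so the set covers the 5 s
response window, and all three are arguments. Binary behaviors get forward
and time-mirrored copies (responses from 5 s before onset to 5 s after
offset); kinematics get causal copies only. The rat-assay variable list
names seven behaviors but counts eight; rat-movement occurrence is used as
the eighth (an interpretation, flagged as such). The per-channel summary
weight is the mean of that channel's coefficients, again a choice the
printed phrase "average GLM weights" leaves open.

## Cross-assay constrained correlation analysis

CoCA finds one neural weight vector per mouse (shared across assays) and
one behavioral weight vector per assay (shared across mice) maximizing the
summed Pearson correlations of the projections over training timepoints.
The optimizer is Adam with analytic gradients (lr = 0.01, beta1 = 0.9,
beta2 = 0.999 — unstated in the source convention, so standard values),
seeded random-normal initialization, best of 5 restarts, and convergence
declared when the objective changes by less than a 1e-7 relative tolerance
over 50 iterations. Adam is not a strict ascent method; objective
decreases beyond 1e-6 are counted and reported
(`n_objective_decreases`), not fatal. Correlation is scale-invariant, so
weights are reported unit-norm with signs flipped toward non-negative
training correlations (flips are per mouse and per assay, so joint
non-negativity holds where it is attainable). The exact behavioral
variable lists are not enumerated in the source convention; the defaults
here are EPM (6): normalized |x|, |y|, speed, head-dip, freeze, location
index; rat (9): distance to rat, mouse speed, rat speed, head-to-rat
angle, approach, escape, freeze, rat movement, distance from the safe
wall. All variables are z-normalized except EPM |x| and |y|, which are
min-max scaled to [0, 1]. Significance compares the fitted test-set
correlation against 1000 random unit-norm neural projections (one-tailed).

## State discovery

k-means clusters neural timepoints (best of 10 seeded initializations per
K by within-cluster sum of squares); AIC = RSS_min(K) + 2 M K with M the
cell count selects K over 1-10 by default. Note the penalty's behavior:
an extra cluster is accepted whenever its RSS gain exceeds 2M, and on
long, low-dimensional recordings such gains are generic, so the selected
K grows with recording length; when comparability with a fixed K matters
the range can be pinned (e.g. `k_range = 3`). The avoidance (approach)
cluster is the one with the minimum (maximum) mean avoidance/approach
score, ties to the lower index. Significance permutes the score labels
over timepoints 100 times, recomputing the extreme cluster means; the
observed approach (avoidance) mean is significant above the 95th (below
the 5th) percentile of its null. Score-label permutation and
neural-permutation phrasings of this null are equivalent here, since only
the pairing of scores with cluster assignments is broken. For cross-assay
transfer, centroids fit on co-registered cells in one assay classify the
withheld assay's timepoints by nearest centroid, and the transferred
approach/avoidance score separation is tested by rank-sum. The HMM
alternative projects activity onto the top principal components reaching
60% variance and fits a 4-state (configurable) diagonal-covariance
Gaussian HMM by EM (10 restarts, 500 iterations, tolerance 1e-6; the
forward-backward recursions are scaled, and the log-likelihood ascent is
asserted in tests); states are decoded by Viterbi and labeled exactly like
k-means clusters. Fitting is per session; score summaries aggregate across
sessions afterwards.

## The synthetic generator

`simulate_behavior_session()` plants ground truth an analysis stage can be
held to. Trajectories are waypoint walks — closed-arm dwell bias on the
EPM, safe-side bias plus occasional near-rat visits in the rat arena —
with background speed held in (0.25, 3) cm/s so only planted events cross
the freeze or dash thresholds. Events are spliced in as scripted speed
profiles with linear ramps: the true noiseless kinematics cross 0.25 or
3 cm/s at an exact frame, and a centered moving average preserves a linear
ramp's crossing point, which is what makes frame-level onset recovery a
well-posed test rather than a circular one. Ground-truth event tables are
derived from those true kinematics by the threshold definitions
themselves. The rat circles its tether point at a gently varying speed
under 0.3 cm/s; planted lunges decay monotonically from their peak and
together occupy more than 0.5% of frames, so the 99.5th speed percentile
always falls inside the lunge speed range and super-threshold frames form
a prefix of each lunge (onsets stay exact under the percentile rule).

Activity: each cell's rate is baseline + tuning x indicator of its
preferred condition (open-category cells follow open-arm occupancy in the
EPM and the approach state in the rat arena; closed-category cells the
mirror; toy-rat sessions carry no tuning), convolved with a
single-exponential calcium kernel (tau = 2 s, GCaMP6s-like — deliberately
slow to stress the 10 s exclusion logic) and Gaussian noise at
`snr` = tuning amplitude / noise SD. Because cell identities and
categories are deterministic given the configuration, paired EPM/rat
sessions share planted coding over the co-registered cells (44% by
default, the observed registration yield), which is what the transfer and
CoCA recovery tests exercise. The optional bleaching artifact is an
additive exponential shared across cells with the session length as decay
constant — the baseline fluorescence decaying, with transients riding on
top — giving a >= 5%-variance slow component the suppression stage can
find. A *multiplicative* ramp on mean-zero fluctuating signals would not
be spectrally slow at all, so it could never satisfy the slow-power
criterion; the additive form is the physical reading of a shared bleach.

What the generator does **not** emulate: real occupancy statistics beyond
qualitative structure, pose-tracking noise unless `pose_jitter_cm` is set,
spike-to-fluorescence nonlinearity, cell-to-cell kernel variability, or
co-registration errors. Passing recovery tests therefore shows the
estimators are correct under their own assumptions, not that those
assumptions hold in any particular recording.

## Numerical choices and degenerate inputs

* Frame conventions: frame i covers [(i-1)/fps, i/fps); event onsets in
  seconds are (first frame - 1)/fps; downsampling drops trailing partial
  blocks; binary channels downsample by any-within-block, categorical by
  block majority.
* Sessions default to 10 minutes in the generator and 5-7 minutes in the
  test fixtures (40-60 cells), which preserves every occupancy and event
  statistic the estimators consume at a fraction of the cost of a full
  20-minute session; the interleaved split needs at least one 60 s block
  plus gap, and errors below that.
* Degenerate inputs fail loudly: zero-variance cells name themselves
  before z-scoring, constant behavioral channels name themselves before
  CoCA normalization, unvisited arms downgrade affected cells to
  "neither" with a warning, empty clusters demand a re-fit, rank-deficient
  regression designs fall back to a small ridge with a warning.
* With a 2 s calcium kernel, state boundaries smear by several neural
  samples; cluster-state overlap on default sessions is therefore bounded
  by transition bleed, and the correspondence test uses a fast-kernel
  (tau = 0.5 s) session to isolate the clustering itself.

## Known limitations

Per-sample significance tests ignore autocorrelation (block-bootstrap and
circular-shift variants of the nulls would tighten this); the head-dip
rule is a geometric surrogate for an unspecified manual procedure; the
AIC penalty's scale-dependence is inherited from its printed form; CoCA's
objective is non-convex, and restarts mitigate but cannot abolish local
optima; the acceptance-level boundary values are analytic properties of
the formulas and deliberately independent of recording scale.
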