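---
title: "Decoding 3D sound location from fMRI multivoxel patterns: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding 3D sound location from fMRI multivoxel patterns: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundloc3d)
```

# The problem

Whether, and where, the human temporal lobe carries information about the
3D position of a sound source is a question for multivariate pattern
analysis (MVPA): per-voxel (univariate) contrasts between sound locations
are typically null, while a linear classifier reading the *pattern* of weak
responses across many voxels can discriminate location categories. This
package implements that analysis as a reusable, fully tested pipeline,
together with a synthetic-data generator so that every stage can be
validated without access to human data.

The emulated experiment: a listener at the centre of a sphere of sixteen
loudspeakers (radius 80 cm; one at the zenith, four at elevation +45°, eight
on the horizontal ring, three at −45°). Sounds recorded in-ear from these
speakers are replayed during sparse-sampling fMRI: each 5.5 s trial starts
with a 2 s volume acquisition, and a 550 ms stimulus is presented at a
uniformly jittered onset within the following 2.5 s, so the stimulus is
heard in silence and its haemodynamic response is sampled by the *next*
acquisitions. A run is 76 trials (64 stimulus — 4 per location — and 12
silent), and a subject contributes 8 runs.

Three binary discriminations are decoded:

| condition | class a | class b | excluded |
|---|---|---|---|
| left vs right | azimuth < 0 (5) | azimuth > 0 (5) | median plane + zenith (6) |
| up vs down | elevation > 0, incl. zenith (5) | elevation < 0 (3) | horizontal ring (8) |
| front vs back | \|azimuth\| < 90° (5) | \|azimuth\| > 90° (4) | ±90° cone + zenith (7) |

Only the left/middle/right memberships are fixed by the behavioural task
description; the up/down and front/back memberships are this package's
design decision. We split up/down on the sign of elevation with the
horizontal ring excluded, and front/back on |azimuth| ≷ 90° with the
±90° cone excluded — the only partitions consistent with the condition
names that leave no ambiguous member. The zenith speaker counts as "up"
(it is maximally up); this is configurable (`include_pole_in_up`). Because
the source experiment never enumerates these sets, the class sizes (5, 5),
(5, 3), (5, 4) are established by enumeration in this package's tests, not
by external authority.

# Pipeline

## Response estimation (GLM)

Each run is fitted separately, per voxel, by ordinary least squares with 18
regressors: one per sound location (the four 550 ms boxcars of that
location convolved with a canonical double-gamma HRF on a 0.1 s grid and
sampled at the acquisition times), a mean-centred linear trend, and an
intercept. The four same-location trials thus share one coefficient,
yielding 16 response amplitudes ("betas") per run and 128 per subject.
Data on this path are never smoothed (`fit_run_glm` refuses volumes marked
smoothed).

The HRF is the standard double-gamma (response gamma with delay 6 s,
undershoot gamma with delay 16 s, ratio 1/6), peak-normalized to 1. A
"within-trial linear trend" with one sample per trial is unidentifiable, so
the trend regressor is a within-run linear drift — the only reading that
both is estimable and makes the drift term in the noise model meaningful.

The univariate check (`univariate_contrast`) smooths each volume with a
5 mm FWHM separable Gaussian (SPM's "5 × 5 × 5 mm" convention read as FWHM
per axis), fits a pooled stimulus-vs-silent design per run, combines runs by
a fixed-effects sum (t = Σβ / √Σse²), and thresholds two-sided p-values by
Benjamini–Hochberg at α = 0.05. Step-up semantics reject adjusted p ≤ α
(the boundary case p·m/k = α rejects).

## Voxel selection by permutation-tested SVM weights

Within the ROI, and **using training runs only**, the class labels of the
feature table (one row per training run × included location) are permuted
`n_perm` times (default 2000); a linear SVM is trained on each permutation
and every voxel's weight is recorded. A Gaussian is fitted to each voxel's
permuted-weight sample (mean, sd), and the true-label weight is converted to
a two-sided tail probability p = 2Φ(−|w − μ|/σ). Voxels with p < 0.05
(strict, the source's stated rule) are selected for that fold.

Two-sided p-values are a deliberate choice: for a linear SVM a strongly
negative weight is exactly as informative as a positive one, and the
underlying description ("lies far outside the major mass") does not pick a
side. One-sidedness would only relabel which class drives a voxel.

Numerical choices: features are standardized per voxel with training-set
statistics (default on; configurable); zero-variance voxels are zeroed,
flagged, given null sd 0 (p = 1 if w = μ, else 0), and are never selected.
If no voxel survives the threshold, the fold falls back to the full ROI and
is flagged rather than aborting, keeping cross-validation balanced.

The SVM itself is an L2-regularized hinge-loss linear machine (C = 1, no
kernel) solved by cyclic dual coordinate descent on the Gram matrix with a
bias-augmentation column. The cyclic sweep makes the solver bitwise
deterministic given the data, and the Gram form makes the permutation loop
cheap: the Gram matrix is computed once per fold and only the label vector
changes. The solver is verified against an independent quadratic-programming
oracle on the identical dual in the test suite.

## Decoding and group inference

Leave-one-run-out cross-validation: for each of the 8 folds, selection is
recomputed from the 7 training runs, the SVM is trained on the selected
voxels, and accuracy is scored on the held-out run's included locations
(10, 8 or 9 patterns depending on condition). The subject's accuracy is the
mean over folds. At the group level a one-sided one-sample t-test compares
subject accuracies with chance (0.5); a raw-accuracy chance of 50% is kept
for comparability even though two conditions are class-imbalanced (5v3,
5v4), and balanced accuracies are reported alongside. With zero variance
across subjects the t statistic is undefined; the result is flagged
degenerate (p = 0 above chance, p = 1 below, p = 0.5 exactly at chance).

## Conjunction across runs and subjects

A voxel selected in **more than four** of a subject's 8 folds (≥ 5) is an
*effective voxel* (EV). An EV shared by **at least 3** subjects is a
*significant effective voxel* (SEV). Treating per-subject EV status as a
Bernoulli trial with success probability p < 0.05, the number of subjects
X sharing a voxel is binomial, and the exact tail is

$$P(X \ge 3) = \sum_{k=3}^{8} \binom{8}{k} p^k (1-p)^{8-k}
  \approx 5.79 \times 10^{-3} \text{ at } p = 0.05 .$$

`binomial_tail()` computes this sum exactly (verified against 2^n
enumeration) rather than quoting any rounded bound.

# The synthetic world

`make_pattern_spec()` fixes the ground truth; `simulate_subject()` draws
data from it. Defaults, chosen once as a plausible desk-scale world:

| parameter | default | meaning |
|---|---|---|
| grid | 24 × 24 × 12 voxels, 3 mm | whole "brain" volume |
| ROI | two ellipsoids, ~616 voxels | bilateral temporal-lobe surrogate |
| baseline amplitude | 2 | common auditory response of every ROI voxel |
| informative voxels | 30 per condition, disjoint | distributed weak code |
| planted amplitude a | 1 | +a for class-a, −a for class-b locations |
| noise sd | 1 | AR(1) innovations, marginal sd |
| AR(1) coefficient | 0.3 | temporal autocorrelation |
| drift | 0.02 / trial | linear scanner drift |
| offset | 100 | raw-signal baseline |

Signal construction: each voxel's time course is the design-matrix
prediction (offset + baseline × summed location regressors + planted
effects × location regressors + drift) plus stationary AR(1) Gaussian
noise, sampled once per trial at the acquisition onset (configurable lag).
One sample per trial is a deliberate abstraction of the 2 s acquisition
window — the downstream analysis consumes exactly one response per trial
bin, so modelling within-acquisition dynamics would add nothing the
pipeline could see. Because the simulator and the design-matrix builder
share the same regressors, a noiseless simulation is an exact least-squares
identity, which the tests exploit (recovery to 1e-8).

What the generator does **not** emulate: head motion, physiological noise,
spatial autocorrelation of noise, subject-specific anatomy or HRF
variability, and any topographic organisation of the planted code (voxels
are drawn uniformly in the ROI). A green decoding test therefore
establishes that the *pipeline* recovers planted, distributed,
sign-coded patterns at realistic noise — not that real cortex encodes
sound location this way.

Per-voxel effect-to-noise of 1 with 30 informative voxels makes per-fold
decoding nearly perfect; the interesting regimes (near-chance decoding,
selection at the edge of detectability) are reached by lowering the
amplitude, which several tests do (amplitude 0 for calibration, 0.3–0.8 for
ordering checks).

All randomness descends from one master seed through named substreams
(`substream(seed, "design.run3")`, "noise.run3", "patterns",
"decode.sub2.left_vs_right", …), so any stage can be reproduced in
isolation and chained CLI stages are bit-identical to a one-shot run.

# Numerical notes and edge cases

* **Smoothing** is separable Gaussian with edge renormalization (divide by
  the smoothed indicator), so constant fields are exactly invariant and
  fwhm → 0 is the identity; total mass is preserved up to the
  renormalized kernel tails. Re-binarizing a smoothed solid mask at a
  strict 0.5 threshold *erodes* convex corners in 3D (evaluated on a 10³
  box: 696 of 1000 voxels survive, faces and interior intact, no outward
  growth); the threshold is configurable where dilation is wanted.
* **Design-matrix rank** is checked per run; collinear columns are named in
  the error (a zeroed HRF, for instance, reports all location columns).
* **Gaussian vs empirical permutation p-values** agree to Kolmogorov
  distance < 0.1 at 500 permutations in the tests; the Gaussian fit is the
  default because it gives sub-resolution p-values at 2000 permutations.
* **NIfTI I/O** is a minimal NIfTI-1 implementation (3D/4D, little-endian,
  `.nii`/`.nii.gz`); volumes are written as float64 so that
  write-then-read is bit-exact, which the stage-composability contract
  relies on.
* Tests run permutation counts of 30–500 for speed; the package default
  honours 2000.

# Known limitations

* The per-fold selection fallback (empty selection → full ROI) biases null
  worlds *toward* chance decoding, which is conservative for the decoding
  claim but means "fallback fold" flags should be inspected on real data.
* The fixed-effects univariate combination assumes homogeneous run
  variance; a mixed-effects second level is out of scope.
* Raw accuracy against a 50% chance level is kept for the two imbalanced
  conditions for comparability; balanced accuracy is reported but not
  tested against chance.
* The binomial SEV bound treats subjects as independent Bernoulli trials
  with a *common* p equal to the selection α; spatial correlation of
  selection within a subject is not modelled.
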