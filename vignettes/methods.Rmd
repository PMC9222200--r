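---
title: "Quantifying infant movement and modeling cerebral-palsy risk"
author: "babymotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infant movement and modeling cerebral-palsy risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(babymotion)
```

## The problem

The General Movements Assessment (GMA) predicts cerebral palsy (CP) from
the quality of an infant's spontaneous movements at 3–5 months corrected
age, but it requires scarce clinical expertise. `babymotion` implements
an automated alternative: ordinary 2D video of a supine infant is reduced
to a handful of kinematic summary features, and a logistic model over
those features ranks CP risk. The package covers the whole workflow —
video screening, skin segmentation, dense optical flow, feature
extraction, and the complete model-development and internal-validation
protocol — plus simulators that generate ground-truthed test data, since
no clinical video or feature data can be redistributed.

## The motion measurements

**Skin model.** Pixels are classified by a single 2D Gaussian over the
chroma plane (Cb, Cr) of BT.601 YCbCr, with a Mahalanobis-distance
threshold set at a quantile (default 0.95) of the training pixels' own
distances. Discarding luma makes the classifier tolerant of moderate
exposure differences, provided the training pixels span a brightness
range; the packaged default model is trained over a 0.7–1.3× gain sweep
of the phantom skin palette. On phantom frames, scaling brightness by
±20% changes the measured skin fraction by under 5% (relative). The
Gaussian sits behind a small interface (`SkinModel` + `classifyPixels`)
so histogram or mixture models could be swapped in. Masks are cleaned by
one morphological opening then closing with a 3×3 box element, which
removes salt-and-pepper errors that would otherwise corrupt pixel
counts; both operators are inclusion-monotone, so the property that a
larger threshold never shrinks the mask survives cleanup.

**Optical flow.** Dense inter-frame displacement is estimated by a
coarse-to-fine iterative Lucas–Kanade method on the luma channel:
box-filter presmoothing (two 3×3 passes), a 2× image pyramid whose
coarsest level is kept at ≥ 32 px, and per level at most 3 warping
iterations solving the windowed (9×9) normal equations with symmetric
(average-image) gradients. Three numerical choices matter and were set
by the package's own oracles rather than convention:

* *Iteration cap.* On weakly textured regions the per-window solution is
  noise-driven; iterating it lets the estimate random-walk, and coarse
  pyramid levels multiply that walk by the upsampling factor. Capping at
  3 iterations/level keeps static-scene flow essentially zero while still
  converging for the displacement range of interest (≤ ~6 px/frame).
* *Conditioning gate.* A pixel's 2×2 system is solved only where the
  structure tensor's smaller eigenvalue exceeds 5e-3; elsewhere the
  update is zero. This suppresses spurious flow in flat or 1D-textured
  regions (the aperture problem).
* *Pyramid floor.* Levels smaller than 32 px alias structures a few
  pixels wide and were observed to bias small displacements upward by
  ~0.3 px; such levels are not built.

The estimator recovers rigid translations of a textured scene to well
within 0.5 px (typically < 0.1 px) and is equivariant under a common
shift of both frames. A border margin (window radius + 2 px) is excluded
from all statistics. The estimator is pluggable behind
`estimateFlow(method = ...)`; fidelity is defined by these behavioral
oracles, not by a specific reference implementation.

**Features.** With fps known, displacements become velocities in
pixels/second (no physical calibration is attempted; units are recorded
in the feature schema). Per frame pair, supported on the skin mask of
the earlier frame:

* quantity of motion `q(t)`: the percentage of skin pixels whose
  displacement exceeds a motion threshold (default 0.5 px/frame — above
  the estimator's static-scene noise floor, validated by the zero-motion
  oracle);
* mean signed and mean absolute horizontal/vertical velocities;
* their first differences × fps (accelerations), and the centroid of the
  moving pixels.

Per video, `summarizeVideo()` produces the feature vector: Q_med, Q_min,
Q_max, Q_mean, Q_sd (sample SD, n−1), V_my, V_mx, signed variants, A_my,
A_mx, and centroid SDs. `V_my` is the mean *absolute* vertical velocity:
under oscillatory movement the signed mean cancels to ≈ 0 for any
symmetric motion, so only the absolute value carries the magnitude
information that a positive published association requires; the signed
variant is emitted alongside for sensitivity analyses. Q statistics use
the 0–100 percentage scale, consistent with a published odds ratio of
1.07–1.08 per unit, which is plausible per percentage point and not per
fraction. Patients with several videos get the unweighted mean of each
feature (`averagePerPatient`).

## The risk model workflow

Model development follows the published protocol exactly, on a
complete-case basis:

1. **Univariate screening** — one single-predictor logistic fit per
   candidate; retain p < 0.20 (Wald). Zero-variance predictors are
   excluded; separated fits fall back to a Firth-penalized fit (written
   here as adjusted-score IRLS) and are flagged.
2. **Collinearity** — iterative pruning while any VIF = 1/(1−R²)
   exceeds 4.0, dropping the worst offender each round; ties drop the
   later name in registry order. Exact collinearity counts as infinite.
3. **Backward selection** — refit, drop the single worst variable with
   p ≥ 0.20, repeat. The full trace is kept in the `ModelSpec`.
4. **Internal validation** — Harrell's bootstrap optimism: refit the
   *fixed* final variable set on each of B resamples, score resample and
   original data, average the C-statistic gap, and subtract it from the
   apparent C. Refitting the fixed set (not the whole selection path) is
   the common reading of validating "the multivariable model"; the
   path-resampling variant is available via `reselect = TRUE`.
   Resamples with a single outcome class are redrawn and counted.
5. **Fit and discrimination** — Hosmer–Lemeshow over deciles of risk
   (χ² over both outcome levels, df = groups − 2, tied deciles collapsed
   with df adjusted) and the concordance C computed by midranks, which
   equals the exhaustive all-pairs count.
6. **Classification** — the ROC threshold maximizing Youden's J (ties
   resolved toward the lower threshold, favoring sensitivity), then the
   confusion matrix and sensitivity/specificity/PPV/NPV/accuracy with
   exact Clopper–Pearson 95% intervals. Zero-denominator metrics are
   reported as NA, never 0.

The packaged published coefficients (`publishedModel()`) carry no
intercept — none was published — so they support risk *ranking* only;
absolute probabilities require a user-supplied or recalibrated
intercept. Standard errors are back-calculated from the published Wald
statistics. One published inconsistency is handled explicitly: the
multivariable Q_sd odds-ratio entry duplicates the V_my row (2.12) and
contradicts its own coefficient (exp(1.13) = 3.10); the coefficient is
taken as authoritative and no check is placed on that entry. Likewise
the published corrected C (0.71), apparent C (0.74) and optimism (0.04)
are not mutually consistent at two decimals, so no exact assertion is
made on corrected C.

## What the simulators emulate

**Phantom videos** stand in for clinic recordings: skin-toned, rigidly
textured ellipses oscillating vertically on a contrasting background,
with per-frame amplitude jitter (movement variability), sensor noise,
and 8-bit quantization. Defaults — 64×64 px, 15 fps, 60 s, four limbs,
amplitude 3 px at 1.2 Hz with jitter SD 1 px, noise SD 0.01 — emulate
small-amplitude, highly variable fidgety-period movement, and place the
generator in the regime where the quantity-of-motion measurement is
informative rather than saturated: at much larger amplitudes every limb
exceeds the motion threshold in almost every frame, the true moving
fraction degenerates to a constant, and agreement statistics become
uninformative (rank correlations against a nearly constant, heavily
tied truth are bounded well below 1 by the tie correction alone). The
analytic sidecar (true moving-area fraction and area-weighted vertical
speed, computed from the limb trajectories, never from the vision
pipeline) tracks the measured q series with Spearman correlation ≈ 0.9
at default noise.

What the phantoms deliberately do not model: deformable or articulated
motion, occlusion, caregiver hands, camera shake, lighting gradients,
clothing, or photo-realistic appearance. Passing phantom tests therefore
demonstrates the measurement chain's correctness on rigid, well-
segmented motion — not clinical performance on real footage.

**Cohort tables** draw features from a multivariate normal and outcomes
from the logistic model. Defaults reproduce the published study
conditions: the four published per-unit coefficients, 11.5% prevalence
(the intercept is solved numerically on the sampled features to hit a
target prevalence within 1e-6), and feature SDs calibrated so each
per-SD effect matches the published univariate Wald statistics at the
original cohort size (V_my 0.64 px/s; Q_med 5.0, Q_sd 0.42, Q_min 0.45
percentage points). The Q-family correlation structure is likewise
identified from the published tables: the univariate coefficients of
Q_sd and Q_min are *inflated* relative to their multivariable ones,
which pins cor(Q_med, Q_sd) ≈ 0.07, cor(Q_med, Q_min) ≈ 0.21 and
cor(Q_sd, Q_min) ≈ −0.36 — more variable motion goes with lower minima.
Under these conditions the full development pipeline recovers all four
variables in ≥ 90% of n = 2000 replicates with ~95% CI coverage and
negligible optimism, which is the property-based stand-in for the
non-reproducible clinical C = 0.74.

## Sizes, tolerances and degenerate inputs

Simulation problem sizes were chosen to make the checked quantities
statistically sharp while keeping a laptop-scale run: 200 replicates of
n = 2000 with B = 200 bootstrap resamples for the pipeline property;
1000 null replicates for the screening level; 300 fitted-model
replicates for Hosmer–Lemeshow calibration; phantoms of 30–100 frames
at 64×64 px for the vision oracles. Tolerances follow the binomial or
empirical spread at those sizes (e.g. ±4% on a 20% retention rate over
1000 replicates). Degenerate inputs are contracts, not crashes: single
frames, inconsistent frame sizes, unknown flow methods, crops out of
bounds, all-identical skin training pixels (regularized, warned),
constant predictors (excluded, warned), separation (penalized, flagged),
single-class outcomes (error for C, redraw for bootstrap), tied risk
deciles (collapsed, df adjusted), empty skin masks (flagged frames,
excluded downstream), and empty final models (allowed, trace explains).

## Known limitations

Pixel velocities are uncalibrated (no cm/s); heterogeneous camera
geometry across sources is only partially normalized by the per-second
scaling. The flow estimator measures consecutive-pair displacement only
— no long-range trajectories — and its per-pixel error (~0.1–0.2 px)
blurs the moving/static decision for displacements near the threshold.
Limb-specific analysis, 3D reconstruction, pose estimation and the
clinical scoring protocol are out of scope. Absolute risk prediction is
unavailable from the packaged coefficients by construction. Video
containers are not decoded; frames must be supplied as an image
directory with a frame-rate sidecar.
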