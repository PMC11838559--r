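---
title: "From multivoxel patterns to individual differences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multivoxel patterns to individual differences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

People differ in how well they can control the contents of working memory —
holding a thought, replacing it, suppressing it, or clearing the mind
entirely. `wmogradients` implements a complete analysis chain relating
individual differences in a composite *thought-control-difficulties* score
(the mean of z-scored WBSI, PSWQ, and RRS-brooding questionnaire totals) to
the organization of parcellated brain activity during four instructed
working-memory control operations: **maintain**, **replace**, **suppress**,
and **clear**.

The chain has six analysis stages, each exposed as ordinary functions and
orchestrated by `analyze_cohort()` / `run_pipeline()`:

1. **Operation RSA** — per parcel, trial patterns are weighted by the
   operation's unthresholded target-vs-others *t*-contrast
   (`compute_contrast_weights()`), correlated across trials
   (`trial_similarity()`, a 288 × 288 matrix per parcel at the study design),
   and the per-operation 72-trial blocks are vectorized and correlated across
   parcels into a regional (parcel × parcel) matrix
   (`regional_rsa_matrix()`).
2. **Windowed resting RSA** — the two concatenated resting runs (z-scored
   per parcel) are cut into non-overlapping 30-s windows
   (`segment_windows()`; 23 windows of 65 points at TR = 0.46 s), a parcel
   correlation matrix is computed per window, and window-to-window similarity
   is the correlation of lower triangles (`rest_rsa_matrix()`).
3. **Task-weighted connectivity** — a unit boxcar per operation convolved
   with the canonical double-gamma response and rectified
   (`build_operation_weights()`) weights a Pearson correlation between every
   parcel pair; correlations are Fisher-transformed with clipping at
   1 − 10⁻⁷ (`weighted_connectivity()`). Rest connectivity is the unweighted
   analogue.
4. **Cortical gradients** — each 360 × 360 matrix is row-thresholded to its
   top 10 % of connections, converted to a normalized-angle affinity
   (1 − arccos(cosine)/π), embedded by diffusion maps (α = 0.5, automatic
   diffusion time), and the first three gradients are Procrustes-aligned to
   a group template built from the mean affinity
   (`gradients_from_matrix()`, `build_group_template()`,
   `align_to_template()`).
5. **Network metrics** — *eccentricity* is a parcel's Euclidean distance
   from the grand-mean center of 3-gradient space, averaged within each
   wmo-network (V, SM, DM, FPC); *within-network dispersion* is the sum of
   Mahalanobis distances of member parcels from the network's coordinate-wise
   median (`parcel_eccentricity()`, `within_network_dispersion()`).
6. **Decoding and regression** — one-vs-other L2-regularized logistic
   classifiers give per-operation accuracies and AUCs under stratified 4-fold
   cross-validation (`ovr_accuracy()`); their first principal component
   (`accuracy_pc()`) anchors a three-stage hierarchical regression of the
   composite score (`screen_regressions()`, `hierarchical_stages()`), with
   Benjamini–Hochberg FDR within each 4 × 4 family of 16 screening models and
   nested-model F-tests between stages.

# The synthetic cohort generator

Raw imaging data for this design are not publicly deposited, so the package
ships a generator (`generate_cohort()`) that emulates the study's design and
the statistical structure the analyses assume, with known ground-truth
couplings for parameter-recovery testing. The defaults are the study's
design constants: 48 subjects; 360 parcels labeled into four wmo-networks;
4 operations × 72 trials; two 750-point resting runs at TR = 0.46 s.

## Pattern model

Each parcel owns four unit-norm voxel prototypes whose pairwise Pearson
correlations equal its network's 4 × 4 *geometry template* (solved by a
Cholesky factor over a zero-mean orthonormal voxel basis, so the expected
trial RSA reproduces the template exactly). The default templates encode
qualitatively distinct configurations — V treats all operations alike
(stimulus-driven), SM groups maintain with replace, DM groups the two
removal operations, FPC keeps all four distinct. These are design choices of
the generator, picked for qualitative plausibility; only their *distinctness
structure* matters downstream.

Trial noise has three parts:

* **Network channels.** Four low-rank (rank 3) noise streams shared across
  parcels. Each parcel draws on them through a *membership weight vector* —
  mostly its own network's channel plus a Dirichlet admixture of the others
  (`network_overlap = 0.3`). Memberships are drawn once per cohort (shared
  "anatomy"), which makes regional similarity structure consistent across
  subjects; without cross-network admixture the regional matrices would be
  block-diagonal and could not support graded cortical gradients at all.
* **Global channel and unique noise.** A fifth stream shared by all parcels
  and full-rank parcel-unique noise. Variance shares are 0.75/0.05/0.20
  (network/global/unique) of a total noise magnitude equal to the prototype
  norm, giving within-operation trial similarities near 0.5 and regional
  within-network correlations around 0.3–0.45 after weighting.
* **In-signal component.** A fraction (`noise_signal_frac = 0.6`) of each
  shared channel lies inside the prototype subspace with loadings shared
  across parcels. This matters: the contrast-weighting step amplifies
  exactly the discriminative dimensions, and shared variability confined to
  the orthogonal complement would be attenuated by weighting — whereas real
  state fluctuations modulate discriminative dimensions too.

An operation-specific parcel-mean offset (scaled to a fixed per-parcel SNR,
`mean_signal_snr = 0.35`) makes parcel-mean features decodable. Pearson
correlation subtracts each trial vector's mean, so these offsets leave RSA
geometry untouched — they are purely the decodability channel.

## Ground-truth couplings

A latent standard-normal difficulty trait drives three couplings, each
scaled by `strength × pnorm(latent)` so doses stay in [0, 1]:

* **Pattern mixing** (default target DM·suppress): blends the cell's parcel
  memberships toward uniform. The cell's parcels drift toward the
  whole-brain average profile, which lowers their eccentricity — the
  mechanism behind the negative DM-suppress eccentricity association.
* **Within-network variability** (default target FPC·suppress): scatters the
  cell's memberships toward parcel-specific random mixtures, deforming the
  network's cloud in gradient space and raising its Mahalanobis dispersion.
* **Label noise**: with probability up to 0.35 × strength, a trial's
  *engagement* (mean-offset) channel follows a different operation,
  degrading decoding accuracy while leaving pattern geometry intact.

Two mechanistic facts shaped these choices and are worth recording. First,
top-k thresholding makes eccentricity respond to the *composition of each
row's retained support*, not to graded changes in retained values; a
coupling must therefore shift which parcels enter the top 10 % (membership
blending does; pure variance reallocation does not). Second, summed
Mahalanobis dispersion is nearly invariant to isotropic rescaling of a
network's cloud — the covariance normalization absorbs it — so the
variability coupling must deform the cloud's *shape* (parcel-wise scatter),
not merely decorrelate its members.

Questionnaire totals are `loading × latent + noise` on the z scale, mapped
into each scale's published range (WBSI 15–75, PSWQ 16–80, RRS-brooding
5–20) by midpoint centering with range/6 spread and clipping; scale totals
are simulated directly because the analysis consumes totals only. The
distributions are chosen for range plausibility; no published score
distributions exist for this sample. Resting runs come from a network
factor model, are standardized per parcel, and are deliberately *uncoupled*
from the trait, mirroring the null resting-state findings.

The generator works at the trial-vector level; TR-level hemodynamics are
not simulated (the downstream mathematics is identical on trial vectors).
The task time series handed to weighted connectivity is a boxcar-level
series of trial parcel-means (6 TRs per trial, 4 TR gaps) plus noise.

## What passing tests do and do not show

The generator reproduces the design counts, the assumed similarity
structures, and linear trait couplings. It does not emulate hemodynamic
autocorrelation, scanner drift, motion artifacts, spatial smoothness, or
non-linear trait effects. Parameter-recovery results therefore demonstrate
that the *pipeline* is faithful (correct sign and usable sensitivity under
the assumed structure), not that the original biological effect sizes are
reproduced.

# Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `window_seconds` | 30 | rest RSA window length (→ 65 points, 23 windows) |
| `top_fraction` | 0.10 | per-row retained connections before affinity |
| `n_components` | 3 | gradients retained |
| `alpha` | 0.5 | anisotropic diffusion normalization |
| `diffusion_time` | 0 | automatic time: scaling λ/(1−λ) |
| `cv_folds` | 4 | stratified decoding folds |
| `lambda_strength` | 1.0 | L2 penalty on the summed-log-likelihood scale (glmnet `lambda = 1/n`) |
| `shrinkage` | 0.05 | Mahalanobis covariance shrinkage γ |
| `fdr_alpha` | 0.05 | BH-FDR threshold per 16-model family |
| `variance_floor` | 0.5 | summed variance-explained for a valid gradient solution |

Defaults with a stated published value use it (30 s, 10 %, 3 components,
FDR 0.05); the rest are the package's own choices: α = 0.5 and automatic
diffusion time are the common defaults of gradient toolboxes; the
regularization strength and fold scheme are unstated in the source analyses
and fixed here for reproducibility; γ = 0.05 stabilizes 3 × 3 network
covariances at ~90 member parcels without visibly biasing distances.

# Numerical and design choices

* **Regional RSA construction.** The parcel × parcel matrix is defined as
  second-order similarity: Pearson correlation, across parcels, of the
  vectorized strictly-lower triangles of each parcel's operation-restricted
  (72 × 72) trial-similarity matrix. It is the construction consistent with
  per-parcel 288 × 288 matrices feeding a 360 × 360 regional matrix.
* **Resting gradient input.** The rest pipeline needs a parcel × parcel
  matrix; the element-wise mean of the per-window parcel correlation
  matrices is used, with the window × window similarity kept for reporting.
* **Thresholding and symmetry.** Row-wise top-k keeps
  `ceiling(0.10 × (n−1))` entries per row (36 at n = 360), ties broken
  toward the lower column index; the resulting asymmetric matrix is
  re-symmetrized by the row-cosine affinity, matching the stated order of
  operations.
* **Alignment.** Individual embeddings are aligned to the group-mean
  template by orthogonal Procrustes (reflections allowed, no scaling).
  Orthogonal maps are isometries, so eccentricity is provably unchanged by
  alignment; dispersion is unchanged up to the rotation sensitivity of the
  coordinate-wise median centroid (a sub-percent effect in practice, ~5 %
  worst case in adversarial tests).
* **Sign conventions.** Each gradient's largest-magnitude loading is made
  positive; accuracy-PC scores are signed so higher scores mean higher mean
  accuracy.
* **Degenerate inputs.** Zero-variance voxels get weight 0 (logged);
  constant trial vectors, parcels, or triangle vectors are flagged and
  zeroed rather than propagating NaN; perfectly correlated pairs are clipped
  before the Fisher transform; an all-zero thresholded row or a disconnected
  affinity graph raises an informative error; coincident network clouds have
  dispersion 0 by convention.
* **z-scoring** of questionnaire scales uses the sample (n−1) standard
  deviation.
* **FDR families.** One BH family per metric class (16 models: 4 networks ×
  4 operations); the four accuracy regressions form their own family.

# Problem sizes used in the test-suite experiments

Structural and oracle tests run on toy inputs (≤ 20 nodes) or single
subjects. Parameter-recovery experiments run 20 cohorts of 48 subjects at
64 parcels × 16 voxels (couplings 0.8) and null calibration on 10 cohorts of
24 subjects at 48 parcels — sizes at which each cohort's chain completes in
seconds while the couplings remain comfortably recoverable (Spearman |ρ|
typically 0.5–0.8 against the composite score). The acceptance script uses
one 64-parcel subject and 20 label permutations for the chance-level AUC
calibration.

# Known limitations

* Eccentricity and dispersion magnitudes depend on the embedding's
  λ/(1−λ) scaling and are only comparable within a family/template; the
  regressions standardize nothing away, but only *associations* are
  interpreted.
* The exact parcel-to-parcel RSA construction and the joint-embedding
  alignment of the original analyses are under-specified in their sources;
  the constructions here (second-order similarity; Procrustes) are
  equivalent-purpose, deterministic choices, and downstream metrics are
  alignment-invariant by design.
* The weighted-connectivity estimator is a weighted Pearson correlation;
  full nuisance regression (motion, physiology) is out of scope for
  synthetic data, though `weighted_connectivity()` accepts optional nuisance
  regressors for real inputs.
* `ovr_accuracy()` operates on parcel-mean features — a desk-scale stand-in
  for voxel patterns in a localizer ROI that preserves the metric's
  definition (one-vs-other accuracy over 288 trials).
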