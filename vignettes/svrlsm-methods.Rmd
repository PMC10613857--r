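---
title: "Multivariate lesion-symptom mapping of depressive symptom domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate lesion-symptom mapping of depressive symptom domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrlsm)
```

## The problem

After a stroke, roughly a third of patients develop depressive symptoms.
Classical lesion-symptom mapping asks which lesion locations are associated
with a behavioural deficit one voxel at a time; multivariate SVR-LSM
(support-vector-regression lesion-symptom mapping) instead models the
behavioural score as a function of **all** lesioned voxels simultaneously,
and recovers per-voxel weights from the fitted model. This package
implements that pipeline for the Montgomery-Åsberg Depression Rating Scale
(MADRS) and its decomposition into five depressive symptom domains, plus
the scaffolding required to validate every stage on synthetic cohorts with
planted ground truth.

The pipeline is, in order:

1. **MADRS scoring** — ten interview items, each 0-6, summed to a 0-60
   global score and grouped into five symptom domains (motivational,
   emotional, cognitive, somatic, anxiety). The standardized domain score is
   the mean item score of the domain, so all domains live on the same 0-6
   scale.
2. **Data-driven corroboration** — principal component analysis of the ten
   items with five retained components, obliquely rotated, with
   regression-method factor scores as alternative behavioural inputs.
3. **Lesion matrix assembly** — binary masks in a common space are stacked
   into a patients-by-voxels design; only voxels lesioned in at least five
   patients are analysed (the minimum lesion threshold).
4. **Correction** — total lesion volume is regressed out of every voxel
   column and out of the behavioural score; stroke severity (NIHSS), age
   and sex are additionally regressed out of the behavioural side.
5. **SVR fit and back-projection** — an epsilon-SVR with RBF kernel
   `K(x, x') = exp(-gamma ||x - x'||^2)` predicts the corrected score from
   the corrected lesion rows; the voxel weight map ("beta map") is the
   back-projection `beta = X' d` of the dual coefficients onto voxel space.
6. **Permutation inference** — the corrected behaviour vector is permuted
   (1000 times at desk scale; 10 000 in the headline configuration), the
   beta map recomputed each time, and the per-voxel p-value estimated as
   `(1 + #extreme) / (1 + B)`. Voxels with `p < 0.005` form the
   significance map, which is then smoothed with a 2 mm FWHM isotropic
   Gaussian and re-binarized at 0.5.
7. **Map comparison** — conceptual-domain maps are compared with their
   matched factor maps by the Dice coefficient
   `DC = 2|X ∩ Y| / (|X| + |Y|)`, banded as low (0-0.19), low-moderate
   (0.20-0.39), moderate (0.40-0.59), moderate-high (0.60-0.79) and high
   (0.80-1.00).
8. **Cohort statistics** — Spearman correlations of each depression score
   with NIHSS, age and lesion volume, a one-way ANOVA by sex, and
   Benjamini-Hochberg FDR across the whole family.

`run_study()` executes the full replica: scoring, factor analysis, eleven
SVR-LSM analyses (global + 5 domains + 5 factor scores), five
domain-vs-factor Dice comparisons, and the statistics table.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `C` | 30 | — | SVR regularization; the published default of the reference SVR-LSM toolbox lineage |
| `gamma` | 5 | 1/voxels² | RBF width, same provenance |
| `epsilon` | 0.1 | score units | SVR tube width, same provenance |
| `n_permutations` | 1000 | — | desk-scale default; the headline configuration uses 10 000. Floor of 100 enforced |
| `p_threshold` | 0.005 | — | voxel-wise significance threshold |
| `min_overlap` | 5 | patients | minimum lesion threshold for a voxel to be analysed |
| `smoothing_fwhm_mm` | 2 | mm | isotropic Gaussian applied to the thresholded map; interpreted as FWHM (`smoothing_units = "sigma"` available) |
| `cv_folds` | 5 | — | cross-validated fit assessment |

Three deliberate conventions deserve a note:

* **Tail direction.** The hypothesis is one-sided: lesion presence is
  associated with *higher* symptom scores. Under this package's
  back-projection (`beta = X' d`, dual coefficients increasing in the
  score) that hypothesis corresponds to the **positive** tail, which is the
  default (`tail = "pos"`). Toolboxes with the opposite sign convention
  call the same test "negatively tailed"; the direction here was fixed
  against a positive-control simulation (a planted voxel driving the score
  receives a positive weight).
* **Smoothing target.** The default smooths the *binarized* map and
  re-binarizes at 0.5, which acts as a despeckler: an isolated significant
  voxel at 1 mm voxels under a 2 mm FWHM kernel has smoothed centre weight
  `(1/2.129)^3 ≈ 0.10 < 0.5` and is removed, while the interior of solid
  clusters is untouched. `smooth_target = "pvalue"` (smooth first,
  threshold after) is available.
* **Permutation scheme.** Only the corrected behaviour vector is permuted
  (simple Freedman-Lane-style permutation); ties count as extreme
  ("as or more extreme"), and the +1 smoothing in the estimator avoids
  p = 0.

## The oblique rotation

No rotation library is part of the package's dependency set, so the
quartimin criterion (direct oblimin with delta 0, the conventional default
behind "oblique rotation") is minimized in-package with Jennrich's gradient
projection algorithm, started at the identity so the solution is
deterministic; each rotated factor is sign-fixed so its largest-magnitude
loading is positive. The implementation is validated in the test suite
against a frozen rotation of a fixed loading matrix computed once with an
independent gradient-projection implementation, to 1e-4. Promax
(`rotation = "promax"`, via `stats::promax`) is offered as the alternative
oblique variant. Factor scores use the regression method
(`W = R^{-1} S`, scores `Z W` on standardized items), matching the use of
factor score coefficients as behavioural inputs.

Retention is fixed at five factors (mirroring the five conceptual domains),
not chosen by a scree or eigenvalue rule; `explained_variance_at()` reports
the cumulative explained variance of the unrotated solution at any k.

## The synthetic cohort generator

No patient data are distributable, so `cohort_spec()` /
`simulate_cohort()` generate cohorts with known ground truth. Defaults
emulate the reference cohort's marginal statistics:

* **Scale.** 200 patients on a 32³ grid at 5 mm voxels (a 16 cm cube), so
  voxel counts convert to realistic lesion volumes.
* **Lesion volumes.** Log-normal in voxels with `mu = 5.0`, `sigma = 1.09`,
  matching a mean of 33.6 cm³ and SD ≈ 51 cm³ moment-wise at this voxel
  size.
* **Lesion shape.** Each lesion is one connected component grown from a
  seed voxel by iterated random dilation (frontier voxels accepted with
  probability 0.7) until the target volume is reached or the grid boundary
  stops growth — the simplest generator with realistic spatial
  autocorrelation.
* **Spatial distribution.** Seed voxels cluster around the centre of the
  seeded hemisphere (truncated Gaussians), emulating the
  middle-cerebral-artery concentration of real infarct cohorts whose
  overlap maps peak centrally. 58% of seeds fall in the right half-grid
  and frontier voxels across the midline are accepted at a reduced rate
  (0.15), reproducing a right:left:bilateral split of roughly 104:81:15.
* **Behaviour.** Latent domain scores follow
  `score_d = effect_d × damage_fraction(region_d) + volume_effect ×
  normalized_volume + N(0, noise_sd²)`; item values are
  `loadings × latent` plus per-item measurement noise
  (`item_noise_sd = 0.9`), affinely mapped from the fixed reference range
  (-0.4, 5.6) to 0-6, rounded half-up and clipped. The per-item noise is
  essential: under the default indicator loadings, items sharing a domain
  would otherwise be identical and the item correlation matrix exactly
  singular. The default of 0.9 puts the cumulative explained variance of
  five components near the low-70s percent reported for real MADRS data.
* **Covariates.** NIHSS ≈ round(N(12.85, 4.56²)) clipped to 0-25, age
  uniform 45-90, sex Bernoulli(0.5), all independent of the latent scores
  by default (so they act as pure confound regressors).
* **Planted regions.** Five adjacent, disjoint 4³ cuboids packed around
  the coverage peak of the right hemisphere, one per domain. Peripheral
  placements would rarely survive the minimum-overlap filter.

All randomness flows through one seed in the spec; `(spec, seed)`
determines the cohort bitwise, and no call mutates the caller's RNG state.

**What the generator does not emulate:** vascular territories and their
boundary geometry, haemorrhagic lesions, scanner noise and segmentation
error, spatial normalization artefacts, and any dependence of covariates on
lesion anatomy. Passing tests on these cohorts therefore demonstrate the
statistical machinery (calibration, recovery, invariances), not performance
on real clinical images.

## Numerical choices and degenerate inputs

* Masks are binarized at > 0.5 on read, tolerating interpolated masks.
* Voxel coordinates are 0-based array indices; world coordinates exist
  only through the stored affine. Retained voxels are ordered
  lexicographically by (x, y, z).
* Residualization uses QR-based least squares; a constant lesion-volume
  vector or rank-deficient confound design is an error, as are constant
  behaviour (nothing to fit), constant MADRS item columns (factor scores
  need `R^{-1}`), and a Dice comparison of two empty maps (undefined).
* The RBF Gram matrix is computed once per lesion dataset and shared
  across the eleven analyses and all permutation refits; the SVR dual
  solutions come from kernlab's SMO solver and the back-projection is an
  exact matrix product (verified against an independent SVR implementation
  to machine precision in the tests).
* Dice values are rounded to two decimals before banding, so values in
  the gaps between the printed band edges are assigned by their 2-dp
  rounding.
* Severity cut-offs default to the conventional MADRS bands (0-6 none,
  7-19 mild, 20-34 moderate, ≥35 severe). These are an assumption — the
  convention is cited, not printed, in the source literature — and are
  configurable.
* Cluster labelling uses 26-connectivity components; atlas codes missing
  from the label table are reported as "unlabelled".

## Validation design and problem sizes

The test suite exercises every stage at sizes chosen to keep the default
run in minutes:

* **Oracles.** Dice against brute-force set arithmetic (100 random pairs);
  lesion matrix against per-voxel recounts; residuals against per-column
  `lm` fits; smoothing against a direct 3D convolution; the rotation
  against frozen independent values; Spearman/BH/ANOVA against hand
  computations and algebraic identities (two-group F = t²).
* **Null calibration.** 20 independent null cohorts (behaviour independent
  of lesions) at n = 200 on 32³ with 1000 permutations each; the pooled
  fraction of voxels with p < 0.005 is checked against the binomial 95%
  interval, and uniformity with a Kolmogorov-Smirnov test on a 50-voxel
  random subsample per run (subsampling because voxel p-values within one
  run are spatially dependent and share one permutation set, which an
  all-voxel KS would mechanically reject). Marginal calibration was
  additionally verified exact on independent single-voxel null runs during
  development.
* **Planted recovery.** One cohort at generator defaults (effect = 2 ×
  noise SD): Dice(map, region) ≥ 0.3, within-region sensitivity ≥ 0.5,
  < 1% of out-of-region voxels flagged. Power at these settings is
  moderate: realized per-patient effects are `effect × damage_fraction`,
  typically well below the nominal 2 SD, so recovery quality varies across
  cohort realizations; the test is deterministic under its fixed seed.
* **Factor recovery.** Items simulated from planted indicator loadings at
  n = 2000 (with smaller lesions so 2000 volume draws fit the grid); mean
  Tucker congruence after optimal column matching ≥ 0.9.
* **Pipeline shape.** The full replica at n = 100 on 24³ with 120
  permutations: exactly 11 significance maps and 5 Dice rows, bitwise
  reproducible under a fixed seed.

## Known limitations

* At 5 mm synthetic voxels the 2 mm FWHM smoothing kernel is sub-voxel and
  effectively the identity; despeckling is only active at ≲ 2 mm voxels
  (it is unit-tested at 1 mm).
* The default hyperparameters (C = 30, gamma = 5) are inherited from the
  reference toolbox lineage. At gamma = 5 the Gram matrix of weakly
  overlapping cohorts approaches the identity; permutation inference
  remains exactly valid (it is a rank statistic), but out-of-sample CV
  correlations are only informative when patients share lesion anatomy.
  `cv_tune()` grid-searches (C, gamma) by CV correlation when tuning is
  wanted.
* Whether confounds should also be regressed from the lesion side is left
  as an interface choice (`residualize()` corrects the behavioural side,
  volume is removed from both), matching the ambiguity in common practice.
* No cluster-extent or family-wise correction is applied; thresholding is
  voxel-wise only, by design.
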