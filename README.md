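# svrlsm — multivariate SVR lesion-symptom mapping of post-stroke depression

`svrlsm` maps depressive symptom domains after stroke onto lesion anatomy
with multivariate support-vector-regression lesion-symptom mapping
(SVR-LSM). It is written for researchers who have per-patient binary lesion
masks in a common space (NIfTI) and MADRS depression interviews, and who
want a tested, fully scriptable version of the following analysis:

* **MADRS scoring** into the 0-60 global sum, five symptom domains
  (motivational, emotional, cognitive, somatic, anxiety; standardized
  domain score = mean item score), and severity categories;
* **data-driven corroboration** of the domains: PCA of the ten items with
  five retained components, oblique (direct oblimin) rotation, and
  regression-method factor scores;
* **SVR-LSM**: the lesion matrix is restricted to voxels lesioned in ≥ 5
  patients, total lesion volume is regressed from both the voxel columns
  and the behavioural score (confounds NIHSS, age, sex from the
  behavioural side), an epsilon-SVR with RBF kernel
  `K(x,x') = exp(-γ‖x−x'‖²)` is fitted, and the voxel weight map is the
  back-projection `β = Xᵀd` of the dual solution. Voxel-wise p-values come
  from permutations of the corrected score,
  `p = (1 + #{β_perm ≥ β_obs}) / (1 + B)`; the map thresholded at
  `p < 0.005` is smoothed with a 2 mm FWHM Gaussian and re-binarized;
* **map comparison**: Dice coefficient `DC = 2|X∩Y| / (|X| + |Y|)` between
  domain and factor maps, with the conventional similarity bands, plus
  atlas-based cluster labelling;
* **cohort statistics**: Spearman correlations with NIHSS/age/volume,
  one-way ANOVA by sex, Benjamini-Hochberg FDR;
* a **synthetic cohort generator** (`simulate_cohort()`) producing
  connected, hemisphere-biased lesions with log-normal volumes and MADRS
  items driven by planted critical regions — so the entire pipeline is
  testable end-to-end with known ground truth.

`run_study()` orchestrates the full replica: eleven SVR-LSM analyses
(global + 5 domains + 5 factor scores) and five domain-vs-factor Dice
comparisons, reproducible bit-for-bit under a fixed seed.

## Worked example

```r
library(svrlsm)

spec   <- cohort_spec(n_patients = 200, seed = 7)   # emulated cohort
cohort <- simulate_cohort(spec)
cohort
#> <synthetic_cohort> 200 patients, grid 32x32x32, sides R:L:B = 118:76:6

scores <- score_madrs(cohort$behaviour)
madrs_cohort_summary(scores$global)
#>   category count percent
#> 1     none    62    31.0
#> 2     mild   131    65.5
#> 3 moderate     7     3.5
#> 4   severe     0     0.0

fs <- fit_factors(cohort$behaviour)                  # PCA + oblimin
explained_variance_at(fs, 5)
#> [1] 77.3  # percent

lmat <- build_lesion_matrix(cohort$masks, min_overlap = 5)
lmat
#> <lesion_matrix> 200 patients x 4332 voxels (min overlap 5), grid 32x32x32

cfg <- svrlsm_config(n_permutations = 1000, seed = 7)
res <- svrlsm_run(lmat, scores$motivational,
                  cohort$behaviour[, c("nihss", "age", "sex")], cfg)
sum(res$sig_map$grid)
#> [1] 277   # voxels with p < 0.005 after smoothing

# how well does the map recover the planted motivational region?
reg <- spec$critical_regions$motivational
rg  <- array(0L, spec$grid_shape); rg[reg] <- 1L
dice(res$sig_map$grid, rg)
#> <dice_result> DC = 0.317 (low-moderate); |X| = 277, |Y| = 64, |X^Y| = 54
```

The significance map covers 54 of the 64 planted voxels (84% sensitivity);
the remaining flagged voxels are the spatial halo of lesions that overlap
the region — the practical resolution limit of lesion data. The severity
distribution, lesion volumes (mean 34.6 cm³ here) and hemispheric split are
emergent properties of the generator's defaults, which emulate a typical
early-rehabilitation stroke cohort.

A thin command-line wrapper for the full study replica is installed at
`inst/scripts/run-study.R`:

```sh
Rscript inst/scripts/run-study.R --simulate --n-patients 200 --seed 7 --out results/
Rscript inst/scripts/run-study.R --masks masks/ --behaviour behaviour.csv --out results/
```

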