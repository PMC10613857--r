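#' Default planted critical regions
#'
#' Five small cuboid regions, one per depressive symptom domain, placed in
#' the right half of the grid (mirroring the right-hemisphere excess of the
#' emulated cohort) at distinct locations along the anterior-posterior and
#' inferior-superior axes.
#'
#' @param grid_shape 3D grid dimensions.
#' @param size Edge length of each cuboid region in voxels.
#' @return Named list of v x 3 integer matrices of 1-based voxel coordinates.
#' @export
default_critical_regions <- function(grid_shape, size = 4L) {
  stopifnot(all(grid_shape >= 8L))
  domains <- c("motivational", "emotional", "cognitive", "somatic", "anxiety")
  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  x0 <- min(nx - size, floor(nx * 0.65))
  # pack the five regions around the coverage peak of the seeded hemisphere
  # (lesion seeds cluster centrally); boxes are adjacent but disjoint
  yb <- ny %/% 2L - size %/% 2L - 1L
  zb <- nz %/% 2L - size %/% 2L - 1L
  offsets <- list(c(-size, -size), c(0L, -size), c(size, 0L),
                  c(-size, 0L), c(0L, size))
  regions <- lapply(offsets, function(o) {
    y0 <- max(0L, min(ny - size, yb + o[1L]))
    z0 <- max(0L, min(nz - size, zb + o[2L]))
    as.matrix(expand.grid(x = x0 + seq_len(size),
                          y = y0 + seq_len(size),
                          z = z0 + seq_len(size)))
  })
  names(regions) <- domains
  regions
}

#' Default latent-domain to MADRS-item loading matrix
#'
#' Indicator loadings assigning each of the 10 items to exactly one of the
#' five symptom domains (the conceptual item grouping), so that each item
#' inherits the latent score of its domain.
#'
#' @param scheme A domain scheme as returned by [madrs_domain_scheme()].
#' @return 10 x 5 numeric matrix, rows = items, columns = domains.
#' @export
default_factor_loadings <- function(scheme = madrs_domain_scheme()) {
  L <- matrix(0, 10L, length(scheme),
              dimnames = list(paste0("item_", 1:10), names(scheme)))
  for (d in names(scheme)) L[scheme[[d]], d] <- 1
  L
}

#' Specify a synthetic lesion cohort
#'
#' Defines the generating conditions for a simulated stroke cohort: grid
#' geometry, log-normal lesion volumes, hemispheric seeding bias, planted
#' critical regions whose damage drives latent symptom-domain scores, the
#' latent-to-item loading matrix, and noise. Defaults emulate the reference
#' cohort: 200 patients, a right-hemisphere lesion excess, mean lesion
#' volume about 33.6 cm^3 with a long right tail, and MADRS items generated
#' from five latent domains.
#'
#' @param n_patients Number of patients (>= 1).
#' @param grid_shape 3D grid dimensions, each >= 8.
#' @param voxel_size_mm Isotropic voxel edge in mm. The default 5 mm puts a
#'   32^3 grid at head scale so that voxel counts convert to realistic cm^3.
#' @param critical_regions Named list of voxel-coordinate matrices (1-based);
#'   one entry per symptom domain.
#' @param effect_sizes Per-domain weight of critical-region damage fraction
#'   on the latent domain score (named vector or scalar recycled).
#' @param volume_effect Weight of normalized lesion volume on every latent
#'   domain score.
#' @param noise_sd SD of Gaussian noise added to each latent domain score.
#' @param item_noise_sd SD of per-item Gaussian measurement noise added on
#'   top of the loading-weighted latent scores. Without it, items sharing a
#'   domain under indicator loadings would be identical and the item
#'   correlation matrix singular; with it, within-domain correlations are
#'   high but below 1, as in interview data.
#' @param hemisphere_ratio Fraction of lesion seed voxels placed in the
#'   right half-grid (x above the midline).
#' @param volume_lognormal_params c(mu, sigma) of lesion volume in voxels.
#'   Defaults give mean exp(mu + sigma^2/2) of about 269 voxels = 33.6 cm^3
#'   at 5 mm voxels, with coefficient of variation matching a 50.9/33.6
#'   mean-to-SD ratio.
#' @param factor_loadings 10 x 5 matrix mapping latent domain scores to the
#'   10 MADRS items.
#' @param item_reference_range Fixed affine reference range: a latent item
#'   value at the lower end maps to 0 and at the upper end to 6, before
#'   round-half-up and clipping to the 0-6 integer scale.
#' @param seed Integer seed; (spec, seed) fully determines the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200L,
                        grid_shape = c(32L, 32L, 32L),
                        voxel_size_mm = 5,
                        critical_regions = default_critical_regions(grid_shape),
                        effect_sizes = 2,
                        volume_effect = 1,
                        noise_sd = 1,
                        item_noise_sd = 0.9,
                        hemisphere_ratio = 0.58,
                        volume_lognormal_params = c(mu = 5.0, sigma = 1.09),
                        factor_loadings = default_factor_loadings(),
                        item_reference_range = c(-0.4, 5.6),
                        seed = 1L) {
  stopifnot(n_patients >= 1L, length(grid_shape) == 3L, all(grid_shape >= 8L),
            hemisphere_ratio >= 0, hemisphere_ratio <= 1,
            length(volume_lognormal_params) == 2L,
            volume_lognormal_params[2L] >= 0,
            nrow(factor_loadings) == 10L, ncol(factor_loadings) == 5L,
            length(item_reference_range) == 2L,
            diff(item_reference_range) > 0)
  for (nm in names(critical_regions)) {
    r <- critical_regions[[nm]]
    if (!is.matrix(r) || ncol(r) != 3L)
      stop_fmt("critical region '%s' must be a v x 3 coordinate matrix", nm)
    if (any(r < 1L) || any(sweep(r, 2L, grid_shape, `>`)))
      stop_fmt("critical region '%s' has voxels outside the grid", nm)
  }
  if (length(effect_sizes) == 1L)
    effect_sizes <- stats::setNames(rep(effect_sizes, length(critical_regions)),
                                    names(critical_regions))
  stopifnot(length(effect_sizes) == length(critical_regions))
  structure(
    list(n_patients = as.integer(n_patients),
         grid_shape = as.integer(grid_shape),
         voxel_size_mm = voxel_size_mm,
         critical_regions = critical_regions,
         effect_sizes = effect_sizes,
         volume_effect = volume_effect,
         noise_sd = noise_sd,
         item_noise_sd = item_noise_sd,
         hemisphere_ratio = hemisphere_ratio,
         volume_lognormal_params = volume_lognormal_params,
         factor_loadings = factor_loadings,
         item_reference_range = item_reference_range,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# 6-connected neighbours of voxels given as a v x 3 coordinate matrix,
# clipped to the grid.
voxel_neighbours <- function(coords, grid_shape) {
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- do.call(rbind, lapply(seq_len(6L), function(k)
    sweep(coords, 2L, offsets[k, ], `+`)))
  ok <- out[, 1L] >= 1L & out[, 1L] <= grid_shape[1L] &
        out[, 2L] >= 1L & out[, 2L] <= grid_shape[2L] &
        out[, 3L] >= 1L & out[, 3L] <= grid_shape[3L]
  out[ok, , drop = FALSE]
}

# Grow one connected lesion from a seed voxel by iterated random dilation:
# each step accepts a random subset of the current frontier until the target
# volume is reached or growth is stopped by the grid boundary. Candidate
# voxels on the far side of the x midline are accepted with a reduced
# probability, so lesions occasionally extend bilaterally but stay
# predominantly within their seeded hemisphere.
grow_lesion <- function(grid_shape, seed_voxel, target_volume,
                        accept_prob = 0.7, midline_cross_prob = 0.3) {
  inside <- array(FALSE, grid_shape)
  inside[seed_voxel[1L], seed_voxel[2L], seed_voxel[3L]] <- TRUE
  n_in <- 1L
  mid <- grid_shape[1L] / 2
  seed_right <- seed_voxel[1L] > mid
  lin <- function(m) (m[, 3L] - 1L) * grid_shape[1L] * grid_shape[2L] +
    (m[, 2L] - 1L) * grid_shape[1L] + m[, 1L]
  frontier <- voxel_neighbours(matrix(seed_voxel, 1L), grid_shape)
  frontier <- frontier[!inside[lin(frontier)], , drop = FALSE]
  while (n_in < target_volume && nrow(frontier) > 0L) {
    same_side <- (frontier[, 1L] > mid) == seed_right
    p <- ifelse(same_side, accept_prob, midline_cross_prob)
    take <- which(stats::runif(nrow(frontier)) < p)
    if (length(take) == 0L)
      take <- sample.int(nrow(frontier), 1L)
    if (length(take) > target_volume - n_in)
      take <- take[sample.int(length(take), target_volume - n_in)]
    newv <- frontier[take, , drop = FALSE]
    inside[lin(newv)] <- TRUE
    n_in <- n_in + nrow(newv)
    cand <- rbind(frontier[-take, , drop = FALSE],
                  voxel_neighbours(newv, grid_shape))
    cand <- cand[!inside[lin(cand)], , drop = FALSE]
    cand <- cand[!duplicated(lin(cand)), , drop = FALSE]
    frontier <- cand
  }
  inside * 1L
}

#' Generate spatially coherent synthetic lesion masks
#'
#' Each mask is a single connected component grown from a random seed voxel
#' by iterated random dilation until its target volume, drawn from the
#' configured log-normal, is reached (or the grid boundary stops growth).
#' Seed voxels fall in the right half-grid with probability
#' `hemisphere_ratio`. Identical spec and seed give a bitwise-identical
#' cohort.
#'
#' @param spec A [cohort_spec()].
#' @return List of [lesion_mask()] objects, one per patient.
#' @export
generate_lesions <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gs <- spec$grid_shape
  capacity <- prod(gs)
  mu <- spec$volume_lognormal_params[1L]
  sigma <- spec$volume_lognormal_params[2L]
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_patients), function(i) {
      vol <- max(1, round_half_up(stats::rlnorm(1L, mu, sigma)))
      if (vol > capacity)
        stop_fmt("target lesion volume draw for patient %d (%d voxels) exceeds grid capacity (%d voxels)",
                 i, vol, capacity)
      right <- stats::runif(1L) < spec$hemisphere_ratio
      mid <- gs[1L] %/% 2L
      # seed voxels cluster around the centre of the seeded hemisphere,
      # emulating the middle-cerebral-artery concentration of real infarcts
      # (cohort overlap maps peak centrally, not at the periphery)
      trunc_norm <- function(centre, sd, lo, hi) {
        v <- round_half_up(stats::rnorm(1L, centre, sd))
        min(hi, max(lo, v))
      }
      x <- if (right) trunc_norm(mid + gs[1L] / 4, gs[1L] / 10, mid + 1L, gs[1L])
           else trunc_norm(gs[1L] / 4, gs[1L] / 10, 1L, mid)
      seed_voxel <- c(x,
                      trunc_norm(gs[2L] / 2, gs[2L] / 7, 1L, gs[2L]),
                      trunc_norm(gs[3L] / 2, gs[3L] / 7, 1L, gs[3L]))
      grid <- grow_lesion(gs, seed_voxel, vol)
      lesion_mask(grid, voxel_size_mm = spec$voxel_size_mm,
                  patient_id = sprintf("P%03d", i))
    })
  })
}

#' Fraction of a region covered by a lesion
#'
#' @param mask A [lesion_mask()].
#' @param region v x 3 matrix of 1-based voxel coordinates.
#' @return `|lesion intersect region| / |region|`, in `[0, 1]`.
#' @export
damage_fraction <- function(mask, region) {
  stopifnot(inherits(mask, "lesion_mask"), is.matrix(region), ncol(region) == 3L)
  sum(mask$grid[region]) / nrow(region)
}

#' Classify lesion side
#'
#' A lesion is right- or left-sided when at least `1 - bilateral_frac` of its
#' voxels lie in that half-grid; otherwise bilateral.
#'
#' @param mask A [lesion_mask()].
#' @param bilateral_frac Minority-side fraction above which the lesion counts
#'   as bilateral.
#' @return One of `"right"`, `"left"`, `"bilateral"`.
#' @export
lesion_side <- function(mask, bilateral_frac = 0.05) {
  idx <- which(mask$grid == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_character_)
  fr <- mean(idx[, 1L] > dim(mask$grid)[1L] / 2)
  if (fr >= 1 - bilateral_frac) "right"
  else if (fr <= bilateral_frac) "left"
  else "bilateral"
}

#' Generate behavioural data from lesion masks
#'
#' Latent domain scores follow the planted model: for patient i and domain d,
#' `score_d(i) = effect_size_d * damage_fraction(i, region_d) +
#' volume_effect * normalized_volume(i) + N(0, noise_sd^2)`, where
#' normalized volume is lesion volume divided by the cohort maximum. Item
#' values are `factor_loadings %*% latent`, affinely mapped from the fixed
#' reference range to `[0, 6]`, rounded half-up and clipped to integers.
#' NIHSS, age and sex are drawn independently of the latent scores.
#'
#' @param masks List of [lesion_mask()] from [generate_lesions()].
#' @param spec The [cohort_spec()] used to generate the masks.
#' @return List with `behaviour` (data.frame: patient_id, item_1..item_10,
#'   nihss, age, sex) and `damage_fractions` (n x 5 matrix).
#' @export
generate_behaviour <- function(masks, spec) {
  stopifnot(inherits(spec, "cohort_spec"), length(masks) >= 1L)
  if (!identical(dim(masks[[1L]]$grid), spec$grid_shape))
    stop_fmt("mask grid %s does not match spec grid %s",
             paste(dim(masks[[1L]]$grid), collapse = "x"),
             paste(spec$grid_shape, collapse = "x"))
  n <- length(masks)
  regions <- spec$critical_regions
  dmg <- vapply(regions, function(r)
    vapply(masks, damage_fraction, numeric(1L), region = r),
    numeric(n))
  dmg <- matrix(dmg, n, length(regions),
                dimnames = list(NULL, names(regions)))
  vols <- vapply(masks, function(m) sum(m$grid), numeric(1L))
  nv <- vols / max(vols)
  with_seed(derive_seed(spec$seed, 1L), {
    latent <- sweep(dmg, 2L, spec$effect_sizes[colnames(dmg)], `*`) +
      spec$volume_effect * nv +
      matrix(stats::rnorm(n * ncol(dmg), 0, spec$noise_sd), n)
    item_vals <- latent %*% t(spec$factor_loadings) +
      matrix(stats::rnorm(n * 10L, 0, spec$item_noise_sd), n)
    lo <- spec$item_reference_range[1L]
    hi <- spec$item_reference_range[2L]
    items <- round_half_up(6 * (item_vals - lo) / (hi - lo))
    items[items < 0] <- 0
    items[items > 6] <- 6
    storage.mode(items) <- "integer"
    colnames(items) <- paste0("item_", 1:10)
    behaviour <- data.frame(
      patient_id = vapply(masks, `[[`, "", "patient_id"),
      items,
      nihss = as.integer(pmin(25, pmax(0, round_half_up(stats::rnorm(n, 12.85, 4.56))))),
      age = round(stats::runif(n, 45, 90), 1),
      sex = stats::rbinom(n, 1L, 0.5),
      stringsAsFactors = FALSE)
  })
  list(behaviour = behaviour, damage_fractions = dmg)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: `masks`, `behaviour`,
#'   and `ground_truth` (critical regions and per-patient damage fractions).
#' @export
simulate_cohort <- function(spec) {
  masks <- generate_lesions(spec)
  beh <- generate_behaviour(masks, spec)
  structure(
    list(masks = masks,
         behaviour = beh$behaviour,
         ground_truth = list(critical_regions = spec$critical_regions,
                             damage_fractions = beh$damage_fractions),
         spec = spec),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  sides <- table(factor(vapply(x$masks, lesion_side, ""),
                        levels = c("right", "left", "bilateral")))
  cat(sprintf("<synthetic_cohort> %d patients, grid %s, sides R:L:B = %s\n",
              length(x$masks), paste(x$spec$grid_shape, collapse = "x"),
              paste(sides, collapse = ":")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Masks as gzipped NIfTI, behaviour as CSV, ground truth as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$masks)
    write_lesion_mask(m, file.path(dir, "masks", paste0(m$patient_id, ".nii.gz")))
  utils::write.csv(cohort$behaviour, file.path(dir, "behaviour.csv"),
                   row.names = FALSE)
  gt <- list(
    critical_regions = lapply(cohort$ground_truth$critical_regions,
                              function(r) unname(as.data.frame(r))),
    damage_fractions = as.data.frame(cohort$ground_truth$damage_fractions))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}
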