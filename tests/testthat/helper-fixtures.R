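# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Random binary lesion masks on a small shared grid.
random_masks <- function(n, grid_shape = c(6L, 6L, 6L), p = 0.2,
                         voxel_size_mm = 1, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i)
      lesion_mask(array(rbinom(prod(grid_shape), 1L, p), grid_shape),
                  voxel_size_mm = voxel_size_mm,
                  patient_id = sprintf("P%02d", i)))
  })
}

# A corrected_data object built directly from a design matrix and response,
# bypassing residualization (for unit tests of the SVR stage alone).
make_corrected <- function(X, y, grid_shape = NULL, voxel_size_mm = 1) {
  v <- ncol(X)
  if (is.null(grid_shape)) grid_shape <- c(v, 1L, 1L)
  structure(
    list(lesion_matrix_resid = X, behaviour_resid = y,
         lesion_volumes = rowSums(abs(X)) + 1,
         confounds = NULL,
         voxel_index = cbind(seq_len(v) - 1L, 0L, 0L),
         grid_shape = as.integer(grid_shape),
         voxel_size_mm = rep(voxel_size_mm, 3L),
         affine = diag(c(rep(voxel_size_mm, 3L), 1)),
         min_overlap = 1L,
         patient_ids = sprintf("P%02d", seq_len(nrow(X)))),
    class = "corrected_data")
}

# A pmap object built directly from a 3D array of p-values (1 = null).
make_pmap <- function(p_grid, voxel_size_mm = 1,
                      config = svrlsm_config(n_permutations = 100)) {
  idx <- which(p_grid < 1, arr.ind = TRUE)
  structure(
    list(p = p_grid[idx], beta_obs = rep(0, nrow(idx)),
         voxel_index = idx - 1L,
         grid_shape = dim(p_grid),
         voxel_size_mm = rep(voxel_size_mm, 3L),
         affine = diag(c(rep(voxel_size_mm, 3L), 1)),
         config = config),
    class = "pmap")
}

# 3D indicator grid from a v x 3 coordinate matrix.
region_grid <- function(coords, grid_shape) {
  g <- array(0L, grid_shape)
  g[coords] <- 1L
  g
}

# Small synthetic cohort for fast end-to-end tests.
small_cohort_spec <- function(seed = 1, n = 60, gs = c(12L, 12L, 12L), ...) {
  cohort_spec(n_patients = n, grid_shape = gs, voxel_size_mm = 5,
              critical_regions = default_critical_regions(gs, size = 2L),
              volume_lognormal_params = c(mu = 3, sigma = 0.8),
              seed = seed, ...)
}
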