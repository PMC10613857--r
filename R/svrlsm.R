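# The multivariate SVR-LSM core: lesion-volume and confound correction,
# epsilon-SVR model fit with RBF kernel, beta-map back-projection,
# permutation inference, thresholding and smoothing, cross-validation.

#' Configuration of an SVR-LSM analysis
#'
#' Hyperparameter defaults (C = 30, gamma = 5, epsilon = 0.1) follow the
#' published defaults of the reference SVR-LSM toolbox lineage. Permutations
#' default to 1000 at desk scale; the reference analysis used 10 000.
#'
#' @param C SVR regularization constant (> 0).
#' @param gamma RBF kernel width: `K(x, x') = exp(-gamma * ||x - x'||^2)`.
#' @param epsilon SVR tube width (> 0).
#' @param n_permutations Number of behaviour permutations (>= 100).
#' @param p_threshold Voxel-wise significance threshold (reference: 0.005).
#' @param min_overlap Minimum lesion threshold for the voxel filter.
#' @param tail Direction of the one-tailed test. `"pos"` (default) tests
#'   whether lesion presence is associated with higher behavioural scores,
#'   which under this package's back-projection convention corresponds to a
#'   positive voxel weight (the reference toolbox's "negatively tailed"
#'   setting expresses the same hypothesis under its opposite sign
#'   convention). `"neg"` tests the other direction.
#' @param smoothing_fwhm_mm Isotropic Gaussian smoothing kernel applied to
#'   the thresholded map, in mm. Interpreted as FWHM by default.
#' @param smoothing_units `"fwhm"` (default) or `"sigma"`.
#' @param smooth_target `"binary"` (default): binarize the p-map, smooth,
#'   re-binarize at 0.5 (despeckling); `"pvalue"`: smooth the p-map first,
#'   then threshold.
#' @param cv_folds Folds for cross-validated model assessment.
#' @param seed Integer seed driving permutations and fold assignment.
#' @return An object of class `svrlsm_config`.
#' @export
svrlsm_config <- function(C = 30, gamma = 5, epsilon = 0.1,
                          n_permutations = 1000L, p_threshold = 0.005,
                          min_overlap = 5L, tail = c("pos", "neg"),
                          smoothing_fwhm_mm = 2,
                          smoothing_units = c("fwhm", "sigma"),
                          smooth_target = c("binary", "pvalue"),
                          cv_folds = 5L, seed = 1L) {
  tail <- match.arg(tail)
  smoothing_units <- match.arg(smoothing_units)
  smooth_target <- match.arg(smooth_target)
  if (C <= 0 || gamma <= 0 || epsilon <= 0)
    stop_fmt("C, gamma and epsilon must all be positive")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop_fmt("p_threshold must lie strictly between 0 and 1")
  if (n_permutations < 100L)
    stop_fmt("n_permutations must be at least 100 (got %d)", n_permutations)
  structure(
    list(C = C, gamma = gamma, epsilon = epsilon,
         n_permutations = as.integer(n_permutations),
         p_threshold = p_threshold, min_overlap = as.integer(min_overlap),
         tail = tail, smoothing_fwhm_mm = smoothing_fwhm_mm,
         smoothing_units = smoothing_units, smooth_target = smooth_target,
         cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
    class = "svrlsm_config")
}

#' Residualize lesion data and behaviour for volume and confounds
#'
#' Removes the linear effect of total lesion volume from every voxel column
#' of the lesion matrix and from the behavioural score, so that subsequent
#' associations are location-specific rather than driven by lesion size.
#' Confound regressors (e.g. NIHSS stroke severity, age, sex) are removed
#' from the behavioural side together with volume.
#'
#' @param lmat A [build_lesion_matrix()] result.
#' @param behaviour Numeric behavioural score, length n.
#' @param confounds Optional data.frame/matrix of confound regressors
#'   (n rows), residualized from behaviour only.
#' @return An object of class `corrected_data` with `lesion_matrix_resid`,
#'   `behaviour_resid`, `lesion_volumes`, plus the geometry fields of
#'   `lmat`.
#' @export
residualize <- function(lmat, behaviour, confounds = NULL) {
  stopifnot(inherits(lmat, "lesion_matrix"))
  n <- nrow(lmat$data)
  if (length(behaviour) != n)
    stop_fmt("behaviour length %d does not match %d patients",
             length(behaviour), n)
  vol <- lmat$lesion_volumes
  if (stats::sd(vol) == 0)
    stop_fmt("lesion volumes are constant; volume regression is undefined (skip volume correction)")
  Qx <- cbind(1, vol)
  qr_x <- qr(Qx)
  X_resid <- qr.resid(qr_x, lmat$data)
  Qy <- Qx
  if (!is.null(confounds)) {
    Cf <- as.matrix(confounds)
    stopifnot(nrow(Cf) == n)
    Qy <- cbind(Qy, Cf)
  }
  qr_y <- qr(Qy)
  if (qr_y$rank < ncol(Qy))
    stop_fmt("confound design is rank-deficient (rank %d of %d columns)",
             qr_y$rank, ncol(Qy))
  y_resid <- qr.resid(qr_y, as.numeric(behaviour))
  structure(
    list(lesion_matrix_resid = X_resid,
         behaviour_resid = y_resid,
         lesion_volumes = vol,
         confounds = confounds,
         voxel_index = lmat$voxel_index,
         grid_shape = lmat$grid_shape,
         voxel_size_mm = lmat$voxel_size_mm,
         affine = lmat$affine,
         min_overlap = lmat$min_overlap,
         patient_ids = lmat$patient_ids),
    class = "corrected_data")
}

# RBF Gram matrix between rows of X (and optionally rows of X2).
rbf_kernel <- function(X, gamma, X2 = NULL) {
  if (is.null(X2)) {
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  } else {
    D2 <- outer(rowSums(X^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X, X2)
  }
  exp(-gamma * pmax(D2, 0))
}

# Fit epsilon-SVR on a precomputed kernel matrix; returns the full-length
# dual coefficient vector (zero for non-support vectors) and the offset.
fit_svr_dual <- function(K, y, config) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                     C = config$C, epsilon = config$epsilon, scaled = FALSE)
  d <- numeric(length(y))
  d[kernlab::alphaindex(m)] <- kernlab::alpha(m)
  list(dual = d, b = kernlab::b(m))
}

#' Fit the SVR model and back-project the voxel beta map
#'
#' Fits an epsilon-SVR with RBF kernel predicting the residualized
#' behavioural score from the residualized lesion rows, then back-projects
#' the dual solution onto voxel space: `beta = X' d` over the support
#' vectors with dual coefficients `d` (the sensitivity-map convention for
#' the nonlinear kernel). Large-magnitude weights mark voxels whose lesion
#' status drives the score.
#'
#' @param corrected A [residualize()] result.
#' @param config An [svrlsm_config()].
#' @param K Optional precomputed RBF Gram matrix (reused across
#'   permutations and analyses sharing the same lesion data).
#' @return An object of class `beta_map` with `beta` (per retained voxel),
#'   `dual`, `voxel_index` and geometry.
#' @export
fit_beta_map <- function(corrected, config = svrlsm_config(), K = NULL) {
  stopifnot(inherits(corrected, "corrected_data"))
  y <- corrected$behaviour_resid
  if (length(unique(y)) < 2L)
    stop_fmt("behaviour is constant after residualization; nothing to fit")
  X <- corrected$lesion_matrix_resid
  if (is.null(K)) K <- rbf_kernel(X, config$gamma)
  fit <- fit_svr_dual(K, y, config)
  structure(
    list(beta = drop(crossprod(X, fit$dual)),
         dual = fit$dual, b = fit$b,
         voxel_index = corrected$voxel_index,
         grid_shape = corrected$grid_shape,
         voxel_size_mm = corrected$voxel_size_mm),
    class = "beta_map")
}

#' Permutation p-value map
#'
#' Recomputes the beta map under `n_permutations` random permutations of the
#' residualized behaviour vector (simple Freedman-Lane-style permutation of
#' the corrected score) and reports, per voxel,
#' `p = (1 + #extreme) / (1 + n_permutations)` where "extreme" counts
#' permuted weights as or more extreme than the observed weight in the
#' configured tail. The +1 smoothing avoids p = 0 (standard exact-test
#' convention).
#'
#' @param corrected A [residualize()] result.
#' @param config An [svrlsm_config()]; `config$seed` drives the
#'   permutations.
#' @param K Optional precomputed RBF Gram matrix.
#' @return An object of class `pmap`: `p` (per retained voxel), `beta_obs`,
#'   `voxel_index`, geometry, and the config used.
#' @export
permutation_pmap <- function(corrected, config = svrlsm_config(), K = NULL) {
  stopifnot(inherits(corrected, "corrected_data"))
  X <- corrected$lesion_matrix_resid
  y <- corrected$behaviour_resid
  n <- length(y)
  B <- config$n_permutations
  if (lfactorial(n) < log(B))
    warning(sprintf("only %d distinct permutations exist for n = %d; p-values will be coarse",
                    factorial(n), n))
  if (is.null(K)) K <- rbf_kernel(X, config$gamma)
  obs <- fit_beta_map(corrected, config, K = K)
  D <- with_seed(config$seed, {
    vapply(seq_len(B), function(b) fit_svr_dual(K, sample(y), config)$dual,
           numeric(n))
  })
  beta_perm <- crossprod(X, D)  # v x B
  extreme <- switch(config$tail,
                    pos = rowSums(beta_perm >= obs$beta),
                    neg = rowSums(beta_perm <= obs$beta))
  structure(
    list(p = (1 + extreme) / (1 + B),
         beta_obs = obs$beta,
         voxel_index = corrected$voxel_index,
         grid_shape = corrected$grid_shape,
         voxel_size_mm = corrected$voxel_size_mm,
         affine = corrected$affine,
         config = config),
    class = "pmap")
}

# Separable 3D Gaussian convolution with zero padding outside the grid.
# sigma_vox is per-axis in voxel units; sigma 0 leaves the axis untouched.
gaussian_smooth_3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L)
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  smooth_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    r <- max(1L, ceiling(4 * sigma))
    kern <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    kern <- kern / sum(kern)
    n <- dim(a)[axis]
    S <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1L & j <= n
      S[cbind(i[ok], j[ok])] <- kern[o + r + 1L]
    }
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(arr_3d <- a, perm)
    d <- dim(ap)
    m <- S %*% matrix(ap, d[1L])
    aperm(array(m, d), order(perm))
  }
  out <- arr
  for (ax in 1:3) out <- smooth_axis(out, ax, sigma_vox[ax])
  out
}

#' Threshold the p-map and smooth the resulting significance map
#'
#' Binarizes the voxel-wise permutation p-map at `p < p_threshold`, then
#' convolves the binary map with an isotropic Gaussian kernel
#' (sigma = FWHM / 2.3548 converted to voxel units) and re-binarizes at 0.5,
#' which removes isolated significant voxels while leaving the interior of
#' solid clusters unchanged. Voxels outside the minimum-overlap analysis
#' set are never significant. With `smooth_target = "pvalue"` the p-map is
#' smoothed first and thresholded after.
#'
#' @param pmap A [permutation_pmap()] result.
#' @param config An [svrlsm_config()]; defaults to the one stored in `pmap`.
#' @return An object of class `significance_map`: binary 3D `grid`, the
#'   pre-smoothing binary `grid_raw`, and geometry.
#' @export
threshold_and_smooth <- function(pmap, config = NULL) {
  stopifnot(inherits(pmap, "pmap"))
  if (is.null(config)) config <- pmap$config
  thr <- config$p_threshold
  if (thr <= 0 || thr >= 1) stop_fmt("p_threshold must lie in (0, 1)")
  fake_lmat <- list(voxel_index = pmap$voxel_index,
                    grid_shape = pmap$grid_shape)
  sigma_mm <- if (config$smoothing_units == "fwhm")
    config$smoothing_fwhm_mm / 2.3548 else config$smoothing_fwhm_mm
  sigma_vox <- sigma_mm / pmap$voxel_size_mm
  analysis_set <- embed_in_grid(rep(1, length(pmap$p)), fake_lmat) > 0
  if (config$smooth_target == "binary") {
    raw <- embed_in_grid((pmap$p < thr) * 1, fake_lmat)
    sm <- gaussian_smooth_3d(raw, sigma_vox)
    grid <- (sm >= 0.5) * 1L
  } else {
    pgrid <- embed_in_grid(pmap$p, fake_lmat, fill = 1)
    sm <- gaussian_smooth_3d(pgrid, sigma_vox)
    raw <- embed_in_grid((pmap$p < thr) * 1, fake_lmat)
    grid <- (sm < thr) * 1L
  }
  grid[!analysis_set] <- 0L
  storage.mode(raw) <- "integer"
  structure(
    list(grid = grid, grid_raw = raw,
         voxel_size_mm = pmap$voxel_size_mm,
         affine = pmap$affine,
         p_threshold = thr),
    class = "significance_map")
}

#' Cross-validated SVR prediction accuracy
#'
#' Seeded k-fold split; per fold the SVR is fitted on the training rows and
#' out-of-fold behaviour is predicted from the kernel rows against the
#' training support vectors. Reports the Pearson correlation of predicted
#' versus observed residualized behaviour.
#'
#' @param corrected A [residualize()] result.
#' @param config An [svrlsm_config()] (`cv_folds`, `seed`).
#' @param K Optional precomputed RBF Gram matrix.
#' @return List with `correlation`, `predicted`, `observed`, `folds`.
#' @export
cross_validate <- function(corrected, config = svrlsm_config(), K = NULL) {
  stopifnot(inherits(corrected, "corrected_data"))
  y <- corrected$behaviour_resid
  n <- length(y)
  k <- config$cv_folds
  if (k > n) stop_fmt("cv_folds (%d) exceeds number of patients (%d)", k, n)
  X <- corrected$lesion_matrix_resid
  if (is.null(K)) K <- rbf_kernel(X, config$gamma)
  folds <- with_seed(derive_seed(config$seed, 97L),
                     sample(rep(seq_len(k), length.out = n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    fit <- fit_svr_dual(K[tr, tr, drop = FALSE], y[tr], config)
    pred[te] <- drop(K[te, tr, drop = FALSE] %*% fit$dual) - fit$b
  }
  list(correlation = stats::cor(pred, y), predicted = pred, observed = y,
       folds = folds)
}

#' Grid-search SVR hyperparameters by cross-validation
#'
#' @param corrected A [residualize()] result.
#' @param config Base [svrlsm_config()].
#' @param C_grid,gamma_grid Candidate values.
#' @return List with the best `config`, the chosen `C` and `gamma`, and the
#'   full `results` table of CV correlations.
#' @export
cv_tune <- function(corrected, config = svrlsm_config(),
                    C_grid = c(1, 10, 30, 100), gamma_grid = c(1, 5, 10)) {
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  X <- corrected$lesion_matrix_resid
  grid$correlation <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$C <- grid$C[i]; cfg$gamma <- grid$gamma[i]
    cross_validate(corrected, cfg, K = rbf_kernel(X, cfg$gamma))$correlation
  }, numeric(1L))
  best <- which.max(grid$correlation)
  cfg <- config
  cfg$C <- grid$C[best]; cfg$gamma <- grid$gamma[best]
  list(config = cfg, C = cfg$C, gamma = cfg$gamma, results = grid)
}

#' Run one complete SVR-LSM analysis
#'
#' Convenience wrapper: residualize, permutation inference, threshold and
#' smooth.
#'
#' @param lmat A [build_lesion_matrix()] result.
#' @param behaviour Numeric behavioural score, length n.
#' @param confounds Optional confound table (e.g. NIHSS, age, sex).
#' @param config An [svrlsm_config()].
#' @param K Optional precomputed RBF Gram matrix for the residualized
#'   lesion data.
#' @return List with `corrected`, `pmap`, `sig_map`, `beta_obs`.
#' @export
svrlsm_run <- function(lmat, behaviour, confounds = NULL,
                       config = svrlsm_config(), K = NULL) {
  corrected <- residualize(lmat, behaviour, confounds)
  pm <- permutation_pmap(corrected, config, K = K)
  sig <- threshold_and_smooth(pm, config)
  list(corrected = corrected, pmap = pm, sig_map = sig,
       beta_obs = pm$beta_obs)
}
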