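test_that("config validation enforces the documented floors", {
  expect_silent(svrlsm_config())
  expect_error(svrlsm_config(n_permutations = 50), "at least 100")
  expect_error(svrlsm_config(C = -1), "positive")
  expect_error(svrlsm_config(p_threshold = 1.5), "between 0 and 1")
})

test_that("residualization removes volume exactly where it should", {
  masks <- random_masks(20, seed = 61, p = 0.3)
  lmat <- build_lesion_matrix(masks, min_overlap = 1)
  vol <- lmat$lesion_volumes

  # behaviour proportional to volume -> residual vanishes
  corr <- residualize(lmat, 3 * vol)
  expect_lt(max(abs(corr$behaviour_resid)), 1e-10)

  # behaviour orthogonal to [1, volume] -> residual is untouched behaviour
  y <- withr::with_seed(3, rnorm(20))
  y <- qr.resid(qr(cbind(1, vol)), y)
  corr <- residualize(lmat, y)
  expect_equal(corr$behaviour_resid, y, tolerance = 1e-12)

  # residualized behaviour and every lesion column are volume-orthogonal
  y2 <- withr::with_seed(5, rnorm(20))
  conf <- withr::with_seed(7, data.frame(nihss = rpois(20, 10),
                                         age = runif(20, 45, 90),
                                         sex = rbinom(20, 1, 0.5)))
  corr <- residualize(lmat, y2, conf)
  expect_lt(abs(cor(corr$behaviour_resid, vol)), 1e-10)
  cors <- abs(apply(corr$lesion_matrix_resid, 2, cor, y = vol))
  expect_lt(max(cors, na.rm = TRUE), 1e-10)
})

test_that("residual columns match a per-column OLS oracle", {
  masks <- random_masks(20, seed = 67, grid_shape = c(5L, 5L, 2L), p = 0.4)
  lmat <- build_lesion_matrix(masks, min_overlap = 1)
  y <- withr::with_seed(11, rnorm(20))
  corr <- residualize(lmat, y)
  vol <- lmat$lesion_volumes
  for (j in seq_len(min(50, ncol(lmat$data)))) {
    fit <- lm(lmat$data[, j] ~ vol)
    expect_equal(corr$lesion_matrix_resid[, j], unname(resid(fit)),
                 tolerance = 1e-10)
  }
  expect_equal(corr$behaviour_resid, unname(resid(lm(y ~ vol))),
               tolerance = 1e-10)
})

test_that("degenerate residualization inputs error clearly", {
  gs <- c(4L, 4L, 4L)
  g <- array(0L, gs); g[1:4] <- 1L
  masks <- lapply(1:5, function(i) lesion_mask(g, patient_id = paste0("P", i)))
  lmat <- build_lesion_matrix(masks, min_overlap = 1)
  expect_error(residualize(lmat, rnorm(5)), "constant")
  masks2 <- random_masks(10, seed = 71)
  lmat2 <- build_lesion_matrix(masks2, min_overlap = 1)
  expect_error(residualize(lmat2, rnorm(10),
                           data.frame(a = 1:10, b = 2 * (1:10))),
               "rank-deficient")
  expect_error(residualize(lmat2, rnorm(3)), "does not match")
})

test_that("the beta map finds a single noiseless voxel driver", {
  hits <- 0L
  for (rep in 1:20) {
    withr::with_seed(100 + rep, {
      n <- 40; v <- 30
      X <- matrix(rbinom(n * v, 1, 0.3), n, v)
      y <- 2 * X[, 5] + rnorm(n, 0, 0.05)
    })
    corr <- make_corrected(X, y - mean(y))
    bm <- fit_beta_map(corr)
    if (which.max(abs(bm$beta)) == 5 && bm$beta[5] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
})

test_that("beta map agrees with the e1071 radial-kernel SVR oracle", {
  skip_if_not_installed("e1071")
  withr::with_seed(73, {
    n <- 50; v <- 40
    X <- matrix(rbinom(n * v, 1, 0.3), n, v) + 0
    y <- X[, 2] - X[, 7] + rnorm(n, 0, 0.3)
  })
  cfg <- svrlsm_config()
  bm <- fit_beta_map(make_corrected(X, y), cfg)
  m <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                  gamma = cfg$gamma, cost = cfg$C, epsilon = cfg$epsilon,
                  scale = FALSE)
  d <- numeric(n); d[m$index] <- m$coefs
  expect_equal(bm$beta, drop(crossprod(X, d)), tolerance = 1e-6)
})

test_that("beta map is equivariant under joint patient permutation", {
  withr::with_seed(79, {
    n <- 30; v <- 25
    X <- matrix(rbinom(n * v, 1, 0.3), n, v)
    y <- X[, 1] + rnorm(n, 0, 0.5)
    perm <- sample(n)
  })
  b1 <- fit_beta_map(make_corrected(X, y))$beta
  b2 <- fit_beta_map(make_corrected(X[perm, ], y[perm]))$beta
  expect_equal(b1, b2, tolerance = 1e-6)
})

test_that("duplicating every patient preserves the beta sign pattern", {
  withr::with_seed(83, {
    n <- 30; v <- 20
    X <- matrix(rbinom(n * v, 1, 0.3), n, v)
    y <- 2 * X[, 3] - 2 * X[, 9] + rnorm(n, 0, 0.3)
  })
  b1 <- fit_beta_map(make_corrected(X, y))$beta
  b2 <- fit_beta_map(make_corrected(rbind(X, X), c(y, y)))$beta
  big <- abs(b1) > 0.1 * max(abs(b1))
  expect_equal(sign(b1[big]), sign(b2[big]))
})

test_that("permutation p-values respect the estimator's range and boundary", {
  withr::with_seed(89, {
    n <- 60; v <- 20
    X <- matrix(rbinom(n * v, 1, 0.3), n, v)
    y <- 5 * X[, 1] + rnorm(n, 0, 0.1)  # overwhelming signal at voxel 1
  })
  cfg <- svrlsm_config(n_permutations = 200, seed = 4)
  pm <- permutation_pmap(make_corrected(X, scale(y)[, 1]), cfg)
  B <- cfg$n_permutations
  expect_true(all(pm$p >= 1 / (B + 1) & pm$p <= 1))
  # no permutation beats the observed beta at the driver voxel
  expect_equal(pm$p[1], 1 / (B + 1))
  # identical seed reproduces the p-map bitwise
  pm2 <- permutation_pmap(make_corrected(X, scale(y)[, 1]), cfg)
  expect_identical(pm$p, pm2$p)
})

test_that("3D Gaussian smoothing matches a direct convolution oracle", {
  withr::with_seed(97, a <- array(runif(5 * 4 * 3), c(5, 4, 3)))
  sigma <- 0.8
  sm <- svrlsm:::gaussian_smooth_3d(a, sigma)
  r <- ceiling(4 * sigma)
  kern1 <- exp(-(-r:r)^2 / (2 * sigma^2)); kern1 <- kern1 / sum(kern1)
  oracle <- array(0, dim(a))
  for (x in 1:5) for (y in 1:4) for (z in 1:3) {
    acc <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx >= 1 && xx <= 5 && yy >= 1 && yy <= 4 && zz >= 1 && zz <= 3)
        acc <- acc + a[xx, yy, zz] * kern1[dx + r + 1] * kern1[dy + r + 1] *
          kern1[dz + r + 1]
    }
    oracle[x, y, z] <- acc
  }
  expect_equal(sm, oracle, tolerance = 1e-12)
})

test_that("threshold-and-smooth despeckles but preserves solid clusters", {
  gs <- c(16L, 16L, 16L)
  cfg <- svrlsm_config(seed = 1)

  # empty significant set stays empty
  p_grid <- array(1, gs); p_grid[2, 2, 2] <- 0.5  # analyzed, not significant
  sig <- threshold_and_smooth(make_pmap(p_grid), cfg)
  expect_equal(sum(sig$grid), 0L)

  # a solid block survives with its interior intact
  p_grid <- array(1, gs)
  p_grid[5:10, 5:10, 5:10] <- 0.001
  sig <- threshold_and_smooth(make_pmap(p_grid), cfg)
  expect_true(all(sig$grid[6:9, 6:9, 6:9] == 1L))

  # an isolated voxel at 1 mm voxels under a 2 mm FWHM kernel is removed:
  # its smoothed centre weight is (1/(1 + 2*0.5 + 2*0.0625 + ...))^3 < 0.5
  p_grid <- array(1, gs)
  p_grid[8, 8, 8] <- 0.001
  sig <- threshold_and_smooth(make_pmap(p_grid), cfg)
  expect_equal(sum(sig$grid), 0L)
  # the voxel is still significant pre-smoothing
  expect_equal(sum(sig$grid_raw), 1L)
})

test_that("significance never escapes the analyzed voxel set", {
  withr::with_seed(101, {
    gs <- c(10L, 10L, 10L)
    p_grid <- array(1, gs)
    block <- as.matrix(expand.grid(3:6, 3:6, 3:6))
    p_grid[block] <- 0.0001
  })
  pm <- make_pmap(p_grid)
  sig <- threshold_and_smooth(pm, svrlsm_config(seed = 1))
  analyzed <- region_grid(pm$voxel_index + 1L, gs)
  expect_true(all(sig$grid[analyzed == 0L] == 0L))
})

test_that("cross-validation detects planted signal and not pure noise", {
  pos <- 0L
  for (rep in 1:20) {
    withr::with_seed(200 + rep, {
      n <- 40; v <- 30
      X <- matrix(rbinom(n * v, 1, 0.3), n, v)
      y <- 2 * X[, 1] + 2 * X[, 2] + rnorm(n, 0, 0.3)
    })
    # a kernel width at which patient similarity is informative for these
    # unstructured random designs (the analysis default gamma targets
    # spatially coherent lesion data)
    cv <- cross_validate(make_corrected(X, y - mean(y)),
                         svrlsm_config(gamma = 0.05, seed = rep))
    if (cv$correlation > 0) pos <- pos + 1L
  }
  expect_gte(pos, 15L)

  nulls <- vapply(1:50, function(rep) {
    withr::with_seed(300 + rep, {
      X <- matrix(rbinom(30 * 20, 1, 0.3), 30, 20)
      y <- rnorm(30)
    })
    cross_validate(make_corrected(X, y),
                   svrlsm_config(gamma = 0.05, seed = rep))$correlation
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.1)
})

test_that("leave-one-out cross-validation runs and is finite", {
  withr::with_seed(103, {
    X <- matrix(rbinom(15 * 10, 1, 0.4), 15, 10)
    y <- rnorm(15)
  })
  cv <- cross_validate(make_corrected(X, y), svrlsm_config(cv_folds = 15, seed = 2))
  expect_true(is.finite(cv$correlation))
  expect_error(cross_validate(make_corrected(X, y),
                              svrlsm_config(cv_folds = 16, seed = 2)),
               "exceeds")
})

test_that("constant behaviour cannot be fitted", {
  X <- matrix(rbinom(20 * 10, 1, 0.4), 20, 10)
  expect_error(fit_beta_map(make_corrected(X, rep(0, 20))), "constant")
})
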