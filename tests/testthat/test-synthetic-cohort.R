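test_that("forced unit volume produces a single-voxel lesion", {
  spec <- cohort_spec(n_patients = 1, grid_shape = c(8L, 8L, 8L),
                      critical_regions = default_critical_regions(c(8L, 8L, 8L), size = 2L),
                      volume_lognormal_params = c(mu = 0, sigma = 0), seed = 3)
  masks <- generate_lesions(spec)
  expect_length(masks, 1L)
  expect_equal(sum(masks[[1]]$grid), 1L)
})

test_that("the cohort is a deterministic function of (spec, seed)", {
  spec <- small_cohort_spec(seed = 11, n = 12)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(lapply(a$masks, `[[`, "grid"), lapply(b$masks, `[[`, "grid"))
  expect_identical(a$behaviour, b$behaviour)
  c_ <- simulate_cohort(small_cohort_spec(seed = 12, n = 12))
  expect_false(identical(lapply(a$masks, `[[`, "grid"),
                         lapply(c_$masks, `[[`, "grid")))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(500)
  before <- runif(1)
  set.seed(500)
  invisible(simulate_cohort(small_cohort_spec(seed = 1, n = 4)))
  expect_identical(runif(1), before)
})

test_that("hemisphere_ratio 1 places all lesion centroids in the right half", {
  spec <- cohort_spec(n_patients = 100, hemisphere_ratio = 1, seed = 21)
  masks <- generate_lesions(spec)
  cx <- vapply(masks, function(m) {
    idx <- which(m$grid == 1L, arr.ind = TRUE)
    mean(idx[, 1])
  }, numeric(1))
  expect_true(all(cx > spec$grid_shape[1] / 2))
})

test_that("lesions are single connected components", {
  masks <- generate_lesions(small_cohort_spec(seed = 5, n = 10))
  for (m in masks) {
    cc <- svrlsm:::connected_components_3d(m$grid)
    expect_equal(cc$n, 1L)
  }
})

test_that("default volumes emulate the target mean lesion volume", {
  spec <- cohort_spec(n_patients = 200, seed = 7)
  masks <- generate_lesions(spec)
  vols <- vapply(masks, lesion_volume_cm3, numeric(1))
  # generator Monte-Carlo check against its own log-normal target
  expect_lt(abs(mean(vols) - 33.58) / 33.58, 0.25)
})

test_that("a volume draw beyond grid capacity errors and names the draw", {
  spec <- cohort_spec(n_patients = 2, grid_shape = c(8L, 8L, 8L),
                      critical_regions = default_critical_regions(c(8L, 8L, 8L), size = 2L),
                      volume_lognormal_params = c(mu = 10, sigma = 0), seed = 1)
  expect_error(generate_lesions(spec), "exceeds grid capacity")
})

test_that("zero effects and zero noise give the constant baseline item", {
  spec <- small_cohort_spec(seed = 9, n = 8, effect_sizes = 0,
                            volume_effect = 0, noise_sd = 0, item_noise_sd = 0)
  co <- simulate_cohort(spec)
  items <- as.matrix(co$behaviour[, paste0("item_", 1:10)])
  # latent 0 -> scaled value 6*0.4/6 = 0.4 -> rounds to 0
  expect_true(all(items == 0L))
})

test_that("large planted effects make damaged patients score higher", {
  spec <- small_cohort_spec(seed = 13, n = 40, effect_sizes = 50,
                            volume_effect = 0, noise_sd = 0.01,
                            item_noise_sd = 0)
  co <- simulate_cohort(spec)
  sc <- score_madrs(co$behaviour)
  for (d in colnames(co$ground_truth$damage_fractions)) {
    dmg <- co$ground_truth$damage_fractions[, d]
    if (any(dmg > 0) && any(dmg == 0))
      expect_gt(min(sc[[d]][dmg > 0]), max(sc[[d]][dmg == 0]))
  }
})

test_that("planted 5-block structure appears in the item correlations", {
  spec <- cohort_spec(n_patients = 2000, seed = 17,
                      volume_lognormal_params = c(mu = 4, sigma = 1))
  co <- simulate_cohort(spec)
  R <- cor(as.matrix(co$behaviour[, paste0("item_", 1:10)]))
  scheme <- madrs_domain_scheme()
  block <- matrix(FALSE, 10, 10)
  for (d in scheme) block[d, d] <- TRUE
  diag(block) <- NA
  within <- mean(R[which(block)], na.rm = TRUE)
  between <- mean(R[which(!block)], na.rm = TRUE)
  expect_gt(within, between)
})

test_that("damage_fraction matches brute-force set intersection", {
  masks <- random_masks(5, seed = 23)
  region <- as.matrix(expand.grid(x = 2:4, y = 1:3, z = 3:5))
  for (m in masks) {
    lesioned <- which(m$grid == 1L, arr.ind = TRUE)
    key <- function(mm) paste(mm[, 1], mm[, 2], mm[, 3])
    brute <- length(intersect(key(lesioned), key(region))) / nrow(region)
    expect_equal(damage_fraction(m, region), brute)
  }
})

test_that("behaviour table has valid ranges and types", {
  co <- simulate_cohort(small_cohort_spec(seed = 31, n = 25))
  b <- co$behaviour
  items <- as.matrix(b[, paste0("item_", 1:10)])
  expect_true(all(items %in% 0:6))
  expect_true(all(b$nihss %in% 0:25))
  expect_true(all(b$age >= 45 & b$age <= 90))
  expect_true(all(b$sex %in% 0:1))
  expect_true(all(co$ground_truth$damage_fractions >= 0 &
                    co$ground_truth$damage_fractions <= 1))
})

test_that("cohort round-trips through disk formats", {
  co <- simulate_cohort(small_cohort_spec(seed = 37, n = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  m1 <- read_lesion_mask(file.path(dir, "masks", "P001.nii.gz"))
  expect_identical(m1$grid, co$masks[[1]]$grid)
  beh <- read.csv(file.path(dir, "behaviour.csv"))
  expect_equal(beh$item_1, co$behaviour$item_1)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_named(gt, c("critical_regions", "damage_fractions"))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(grid_shape = c(4L, 32L, 32L)), "grid_shape")
  expect_error(cohort_spec(hemisphere_ratio = 1.2), "hemisphere_ratio")
  bad_region <- list(motivational = matrix(c(40L, 1L, 1L), 1),
                     emotional = matrix(1L, 1, 3), cognitive = matrix(2L, 1, 3),
                     somatic = matrix(3L, 1, 3), anxiety = matrix(4L, 1, 3))
  expect_error(cohort_spec(critical_regions = bad_region), "outside the grid")
})
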