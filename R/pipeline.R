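# Full study replica: cohort -> MADRS scoring -> factor analysis -> eleven
# SVR-LSM analyses (global sum, five conceptual domains, five data-driven
# factor scores) -> five domain-vs-factor Dice comparisons -> cohort
# statistics.

# Match each factor to the conceptually corresponding symptom domain by
# maximizing the summed absolute congruence between rotated loading columns
# and the domain indicator columns over all assignments.
match_factors_to_domains <- function(loadings, scheme = madrs_domain_scheme()) {
  ind <- default_factor_loadings(scheme)
  tc <- tucker_congruence(ind, loadings)
  stats::setNames(tc$permutation, colnames(ind))
}

#' Run the full lesion-symptom mapping study replica
#'
#' Executes, in order: MADRS scoring, factor analysis of the items,
#' per-score SVR-LSM for the global sum, the five standardized conceptual
#' domain scores and the five regression-method factor scores (eleven
#' analyses in total), Dice comparison of each domain map with its matched
#' factor map (five comparisons), and the cohort association statistics.
#' Outputs are written under `out_dir` and indexed by a JSON manifest that
#' suffices to re-run the study identically.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()], or a list
#'   with elements `masks` (list of [lesion_mask()]) and `behaviour`
#'   (data.frame with `item_1..item_10`, `nihss`, `age`, `sex`).
#' @param config An [svrlsm_config()].
#' @param out_dir Output directory; created if needed. `NULL` keeps all
#'   results in memory only.
#' @param scheme A [madrs_domain_scheme()].
#' @return An object of class `study_result`: `manifest`, `scores`,
#'   `factors`, `analyses` (named list of per-score results), `dice`
#'   (data.frame of the five comparisons), `stats`.
#' @export
run_study <- function(cohort, config = svrlsm_config(), out_dir = NULL,
                      scheme = madrs_domain_scheme()) {
  stopifnot(inherits(config, "svrlsm_config"))
  t0 <- Sys.time()
  masks <- cohort$masks
  behaviour <- cohort$behaviour
  stopifnot(length(masks) >= 2L, is.data.frame(behaviour))

  # --- scoring -------------------------------------------------------------
  scores <- score_madrs(behaviour, scheme)
  domain_names <- names(scheme)

  # --- factor analysis -----------------------------------------------------
  factors <- fit_factors(behaviour, n_factors = 5L)
  fmatch <- match_factors_to_domains(factors$loadings, scheme)

  # --- lesion matrix and shared corrections --------------------------------
  lmat <- build_lesion_matrix(masks, min_overlap = config$min_overlap)
  confounds <- behaviour[, c("nihss", "age", "sex")]
  score_set <- c(list(global = scores$global),
                 stats::setNames(lapply(domain_names, function(d) scores[[d]]),
                                 domain_names),
                 stats::setNames(lapply(seq_len(5L), function(j)
                   factors$scores[, j]),
                   paste0("factor_", seq_len(5L))))

  # the lesion-side residualization and hence the RBF Gram matrix are shared
  # by all eleven analyses; compute the kernel once
  first <- residualize(lmat, score_set[[1L]], confounds)
  K <- rbf_kernel(first$lesion_matrix_resid, config$gamma)

  analyses <- vector("list", length(score_set))
  names(analyses) <- names(score_set)
  for (i in seq_along(score_set)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    corrected <- if (i == 1L) first
                 else residualize(lmat, score_set[[i]], confounds)
    pm <- permutation_pmap(corrected, cfg, K = K)
    sig <- threshold_and_smooth(pm, cfg)
    analyses[[i]] <- list(pmap = pm, sig_map = sig, config = cfg)
  }

  # --- Dice comparisons: conceptual domain vs matched factor ---------------
  dice_rows <- lapply(domain_names, function(d) {
    f <- paste0("factor_", fmatch[[d]])
    dx <- analyses[[d]]$sig_map
    dy <- analyses[[f]]$sig_map
    if (sum(dx$grid) + sum(dy$grid) == 0L) {
      data.frame(domain = d, factor = f, dc = NA_real_,
                 category = NA_character_, n_x = 0L, n_y = 0L,
                 n_intersection = 0L, stringsAsFactors = FALSE)
    } else {
      dr <- dice(dx, dy)
      data.frame(domain = d, factor = f, dc = dr$dc,
                 category = as.character(dr$category), n_x = dr$n_x,
                 n_y = dr$n_y, n_intersection = dr$n_intersection,
                 stringsAsFactors = FALSE)
    }
  })
  dice_df <- do.call(rbind, dice_rows)

  # --- cohort statistics ---------------------------------------------------
  stat_scores <- cbind(global = scores$global,
                       scores[, domain_names, drop = FALSE])
  covars <- data.frame(nihss = behaviour$nihss, age = behaviour$age,
                       volume_cm3 = lmat$lesion_volumes)
  stats_df <- cohort_statistics(stat_scores, covars, sex = behaviour$sex)

  # --- outputs and manifest ------------------------------------------------
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(analyses)) {
      fp_sig <- file.path(out_dir, paste0("sig_", nm, ".nii"))
      write_lesion_mask(analyses[[nm]]$sig_map$grid, fp_sig,
                        voxel_size_mm = lmat$voxel_size_mm,
                        affine = lmat$affine)
      pgrid <- embed_in_grid(analyses[[nm]]$pmap$p, lmat, fill = 1)
      fp_p <- file.path(out_dir, paste0("pmap_", nm, ".nii"))
      write_lesion_mask(pgrid, fp_p, voxel_size_mm = lmat$voxel_size_mm,
                        affine = lmat$affine)
      files <- c(files, fp_sig, fp_p)
    }
    fp <- file.path(out_dir, "dice.csv")
    utils::write.csv(dice_df, fp, row.names = FALSE)
    files <- c(files, fp)
    fp <- file.path(out_dir, "cohort_statistics.csv")
    utils::write.csv(stats_df, fp, row.names = FALSE)
    files <- c(files, fp)
    fp <- file.path(out_dir, "factor_loadings.csv")
    utils::write.csv(as.data.frame(factors$loadings), fp)
    files <- c(files, fp)
  }
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    n_patients = length(masks),
    n_voxels_analyzed = ncol(lmat$data),
    n_analyses = length(analyses),
    n_significance_maps = length(analyses),
    n_dice_comparisons = nrow(dice_df),
    factor_match = as.list(fmatch),
    significant_voxels = vapply(analyses, function(a) sum(a$sig_map$grid),
                                integer(1L)),
    output_files = as.list(stats::setNames(
      as.character(tools::md5sum(files)), basename(files))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    mf <- manifest
    mf$elapsed_sec <- NULL  # keep the on-disk manifest seed-deterministic
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(manifest = manifest, scores = scores, factors = factors,
         analyses = analyses, dice = dice_df, stats = stats_df,
         lesion_matrix = lmat),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d SVR-LSM analyses on %d patients x %d voxels; %d Dice comparisons\n",
              x$manifest$n_analyses, x$manifest$n_patients,
              x$manifest$n_voxels_analyzed, x$manifest$n_dice_comparisons))
  print(x$dice)
  invisible(x)
}
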