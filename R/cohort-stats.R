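# Sample-level statistics: Spearman correlations of depression scores with
# stroke severity, age and lesion volume; one-way ANOVA by sex; FDR.

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the p-value comes from the
#' asymptotic t approximation (as in `cor.test(..., exact = FALSE)`).
#'
#' @param x,y Numeric vectors of equal length (>= 3, non-constant).
#' @return List with `rho` and `p`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_fmt("Spearman correlation is undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement
#' (`p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' One-way ANOVA of scores by group
#'
#' In the two-group case (e.g. sex) the F statistic equals the squared
#' pooled-variance two-sample t statistic.
#'
#' @param scores Numeric vector.
#' @param group Grouping vector (coerced to factor).
#' @return List with `F`, `p`, `df`.
#' @export
anova_by_group <- function(scores, group) {
  g <- factor(group)
  if (nlevels(droplevels(g)) < 2L)
    stop_fmt("one-way ANOVA needs at least two non-empty groups")
  fit <- stats::anova(stats::lm(scores ~ g))
  list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L],
       df = c(fit$Df[1L], fit$Df[2L]))
}

#' Cohort-level association report
#'
#' Spearman correlations of each depression score with each continuous
#' covariate (NIHSS, age, lesion volume by default) plus a one-way ANOVA of
#' each score by sex, with Benjamini-Hochberg FDR applied across the whole
#' family of tests in one batch (family membership is a single batch by
#' design; restrict the inputs to change it).
#'
#' @param scores data.frame of depression scores (e.g. global plus the five
#'   standardized domains).
#' @param covariates data.frame of continuous covariates to correlate with.
#' @param sex Optional 0/1 (or factor) vector for the ANOVA; omit with
#'   `NULL`.
#' @param alpha Decision threshold applied to FDR-adjusted p-values.
#' @return data.frame with columns `score`, `covariate`, `test`,
#'   `statistic`, `p_raw`, `p_fdr`, `significant`.
#' @export
cohort_statistics <- function(scores, covariates, sex = NULL, alpha = 0.05) {
  scores <- as.data.frame(scores)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(scores) == nrow(covariates))
  rows <- list()
  for (sc in names(scores)) {
    for (cv in names(covariates)) {
      r <- spearman_test(scores[[sc]], covariates[[cv]])
      rows[[length(rows) + 1L]] <- data.frame(
        score = sc, covariate = cv, test = "spearman",
        statistic = r$rho, p_raw = r$p, stringsAsFactors = FALSE)
    }
    if (!is.null(sex)) {
      a <- anova_by_group(scores[[sc]], sex)
      rows[[length(rows) + 1L]] <- data.frame(
        score = sc, covariate = "sex", test = "anova_F",
        statistic = a$F, p_raw = a$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  out$significant <- out$p_fdr < alpha
  out
}
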