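#' The conceptual MADRS symptom-domain scheme
#'
#' Partition of the 10 MADRS items into five depressive symptom domains.
#' Item order: (1) apparent sadness, (2) reported sadness, (3) inner tension,
#' (4) reduced sleep, (5) reduced appetite, (6) concentration difficulties,
#' (7) lassitude, (8) inability to feel, (9) pessimistic thoughts,
#' (10) suicidal thoughts. The default grouping is: motivational = lassitude,
#' inability to feel; emotional = apparent and reported sadness; cognitive =
#' concentration difficulties, pessimistic thoughts, suicidal thoughts;
#' somatic = reduced sleep, reduced appetite; anxiety = inner tension.
#'
#' @param mapping Named list of integer item index sets. Must be a partition
#'   of 1..10 (disjoint, union complete).
#' @return An object of class `domain_scheme`.
#' @export
madrs_domain_scheme <- function(mapping = list(motivational = c(7L, 8L),
                                               emotional = c(1L, 2L),
                                               cognitive = c(6L, 9L, 10L),
                                               somatic = c(4L, 5L),
                                               anxiety = 3L)) {
  items <- unlist(mapping, use.names = FALSE)
  if (anyDuplicated(items))
    stop_fmt("domain scheme item sets must be disjoint")
  if (!setequal(items, 1:10))
    stop_fmt("domain scheme must cover all 10 MADRS items exactly once")
  structure(lapply(mapping, as.integer), class = "domain_scheme")
}

madrs_item_columns <- function() paste0("item_", 1:10)

# Extract and validate an n x 10 integer item matrix from a data.frame,
# matrix, or bare vector of 10 scores.
as_item_matrix <- function(items) {
  if (is.data.frame(items)) {
    cols <- madrs_item_columns()
    if (!all(cols %in% names(items)))
      stop_fmt("behaviour table must contain columns %s",
               paste(setdiff(cols, names(items)), collapse = ", "))
    items <- as.matrix(items[, cols])
  } else if (is.vector(items) && length(items) == 10L) {
    items <- matrix(items, 1L, dimnames = list(NULL, madrs_item_columns()))
  }
  stopifnot(is.matrix(items), ncol(items) == 10L)
  if (any(is.na(items)) || any(items < 0) || any(items > 6) ||
      any(items != round(items)))
    stop_fmt("MADRS items must be integers in 0..6 (violations in %s)",
             paste(unique(which(is.na(items) | items < 0 | items > 6 |
                                  items != round(items),
                                arr.ind = TRUE)[, 2L]), collapse = ", "))
  storage.mode(items) <- "integer"
  items
}

#' Score MADRS records into global sum and symptom domains
#'
#' For each patient, computes the global sum (0-60), per-domain raw sums,
#' and standardized domain scores (raw sum divided by the number of items in
#' the domain), putting every domain on the common 0-6 item scale.
#'
#' @param items Behaviour table with columns `item_1..item_10`, an n x 10
#'   matrix, or a single 10-vector.
#' @param scheme A [madrs_domain_scheme()].
#' @return data.frame with `global` plus, per domain, `<name>_raw` and the
#'   standardized `<name>` column.
#' @export
score_madrs <- function(items, scheme = madrs_domain_scheme()) {
  stopifnot(inherits(scheme, "domain_scheme"))
  M <- as_item_matrix(items)
  out <- data.frame(global = rowSums(M))
  for (d in names(scheme)) {
    raw <- rowSums(M[, scheme[[d]], drop = FALSE])
    out[[paste0(d, "_raw")]] <- raw
    out[[d]] <- raw / length(scheme[[d]])
  }
  out
}

#' Depression severity category from the MADRS global sum
#'
#' Conventional MADRS severity bands are used by default (0-6 none, 7-19
#' mild, 20-34 moderate, >= 35 severe); the cut-offs are configurable since
#' conventions differ between sources.
#'
#' @param global_sum Numeric vector of global sums in `[0, 60]`.
#' @param cutoffs Upper bounds (inclusive) of the none, mild and moderate
#'   bands; everything above the last bound is severe.
#' @return Ordered factor with levels none < mild < moderate < severe.
#' @export
severity_category <- function(global_sum,
                              cutoffs = c(none = 6, mild = 19, moderate = 34)) {
  if (any(is.na(global_sum)) || any(global_sum < 0) || any(global_sum > 60))
    stop_fmt("global MADRS sum must lie in [0, 60]")
  stopifnot(length(cutoffs) == 3L, !is.unsorted(cutoffs))
  cut(global_sum, breaks = c(-Inf, cutoffs, Inf),
      labels = c("none", "mild", "moderate", "severe"),
      ordered_result = TRUE)
}

#' Cohort severity summary
#'
#' Counts and percentages (one decimal) of patients per severity category,
#' either from raw global sums or directly from category counts.
#'
#' @param global_sum Numeric vector of global sums (mutually exclusive with
#'   `counts`).
#' @param counts Named or ordered vector of counts for
#'   (none, mild, moderate, severe).
#' @param cutoffs Passed to [severity_category()] when scoring `global_sum`.
#' @return data.frame with columns `category`, `count`, `percent`.
#' @export
madrs_cohort_summary <- function(global_sum = NULL, counts = NULL,
                                 cutoffs = c(none = 6, mild = 19, moderate = 34)) {
  lev <- c("none", "mild", "moderate", "severe")
  if (is.null(counts)) {
    if (is.null(global_sum) || length(global_sum) == 0L)
      stop_fmt("empty cohort: no global sums or counts supplied")
    counts <- table(severity_category(global_sum, cutoffs))
  } else {
    stopifnot(length(counts) == 4L, all(counts >= 0), sum(counts) > 0)
    counts <- stats::setNames(as.integer(counts), lev)
  }
  n <- sum(counts)
  data.frame(category = factor(lev, levels = lev, ordered = TRUE),
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / n, 1))
}
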