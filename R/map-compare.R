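# Spatial agreement between significance maps: Dice coefficient with the
# published similarity bands, and atlas-based cluster labelling.

as_binary_grid <- function(x) {
  if (inherits(x, "significance_map")) return(x$grid)
  if (inherits(x, "lesion_mask")) return(x$grid)
  stopifnot(length(dim(x)) == 3L)
  (x > 0) * 1L
}

#' Similarity category for a Dice coefficient
#'
#' Closed bands as conventionally printed: low 0-0.19, low-moderate
#' 0.20-0.39, moderate 0.40-0.59, moderate-high 0.60-0.79, high 0.80-1.00.
#' Values are rounded to two decimals before banding, so values falling in
#' the gaps between printed band edges (e.g. 0.195) are assigned by their
#' 2-dp rounding.
#'
#' @param dc Dice coefficient(s) in `[0, 1]`.
#' @return Ordered factor of categories.
#' @export
dice_category <- function(dc) {
  stopifnot(all(dc >= 0 & dc <= 1))
  d2 <- round(dc, 2)
  cut(d2, breaks = c(-Inf, 0.195, 0.395, 0.595, 0.795, Inf),
      labels = c("low", "low-moderate", "moderate", "moderate-high", "high"),
      ordered_result = TRUE)
}

#' Dice coefficient between two binary maps
#'
#' `DC(X, Y) = 2 |X intersect Y| / (|X| + |Y|)` where |X| and |Y| are the
#' significant (or lesioned) voxel counts of the two maps. Both maps must
#' share geometry; the Dice coefficient is undefined when both maps are
#' empty.
#'
#' @param x,y Binary 3D arrays, [lesion_mask()] or `significance_map`
#'   objects with identical grid shape.
#' @return An object of class `dice_result`: `dc`, `n_x`, `n_y`,
#'   `n_intersection`, `category`.
#' @export
dice <- function(x, y) {
  gx <- as_binary_grid(x)
  gy <- as_binary_grid(y)
  if (!identical(dim(gx), dim(gy)))
    stop_fmt("maps differ in grid shape: %s vs %s",
             paste(dim(gx), collapse = "x"), paste(dim(gy), collapse = "x"))
  n_x <- sum(gx)
  n_y <- sum(gy)
  if (n_x + n_y == 0L)
    stop_fmt("Dice coefficient is undefined for two empty maps")
  n_int <- sum(gx * gy)
  dc <- 2 * n_int / (n_x + n_y)
  structure(
    list(dc = dc, n_x = n_x, n_y = n_y, n_intersection = n_int,
         category = dice_category(dc)),
    class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice_result> DC = %.3f (%s); |X| = %d, |Y| = %d, |X^Y| = %d\n",
              x$dc, as.character(x$category), x$n_x, x$n_y, x$n_intersection))
  invisible(x)
}

#' Summarize a set of Dice coefficients
#'
#' Arithmetic mean and sample (n-1) standard deviation, with 2-dp rounded
#' values for reporting.
#'
#' @param dcs Numeric vector of at least two Dice coefficients.
#' @return List with `mean`, `sd`, `mean_2dp`, `sd_2dp`, `n`.
#' @export
summarize_dice_set <- function(dcs) {
  dcs <- vapply(dcs, function(d) if (inherits(d, "dice_result")) d$dc else d,
                numeric(1L))
  if (length(dcs) < 2L)
    stop_fmt("sample SD is undefined for fewer than two Dice values")
  m <- mean(dcs)
  s <- stats::sd(dcs)
  list(mean = m, sd = s, mean_2dp = round(m, 2), sd_2dp = round(s, 2),
       n = length(dcs))
}

# Connected components of a binary 3D grid under 26-connectivity, via the
# adjacency graph of on-voxels.
connected_components_3d <- function(grid) {
  on <- which(grid > 0)
  if (length(on) == 0L)
    return(list(labels = array(0L, dim(grid)), n = 0L))
  d <- dim(grid)
  pos <- integer(prod(d))
  pos[on] <- seq_along(on)
  coords <- arrayInd(on, d)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # half the offsets suffice: each undirected adjacency found once
  offsets <- offsets[seq_len(13L), , drop = FALSE]
  edges <- NULL
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2L, offsets[k, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    lin <- (nb[ok, 3L] - 1L) * d[1L] * d[2L] + (nb[ok, 2L] - 1L) * d[1L] + nb[ok, 1L]
    hit <- pos[lin] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], pos[lin][hit]))
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  labels <- array(0L, d)
  labels[on] <- as.integer(memb)
  list(labels = labels, n = max(memb))
}

#' Label significance-map clusters against an atlas
#'
#' Finds connected components (26-connectivity) of a binary significance
#' map and, for each cluster, tallies its voxels per atlas label, sorted by
#' descending count. Atlas codes missing from the label table are reported
#' as "unlabelled".
#'
#' @param sig_map Binary 3D array or `significance_map`.
#' @param atlas Integer-labelled 3D array sharing the map's geometry.
#' @param label_table data.frame with columns `code` (integer) and `name`.
#' @return data.frame with columns `cluster`, `cluster_voxels`, `label`,
#'   `voxels`, `percent` (of cluster voxels); zero rows for an empty map.
#' @export
label_clusters <- function(sig_map, atlas, label_table) {
  grid <- as_binary_grid(sig_map)
  atlas <- if (length(dim(atlas)) == 3L) atlas else stop_fmt("atlas must be 3D")
  if (!identical(dim(grid), dim(atlas)))
    stop_fmt("atlas grid %s does not match map grid %s",
             paste(dim(atlas), collapse = "x"), paste(dim(grid), collapse = "x"))
  stopifnot(all(c("code", "name") %in% names(label_table)))
  cc <- connected_components_3d(grid)
  out <- list()
  for (cl in seq_len(cc$n)) {
    idx <- which(cc$labels == cl)
    codes <- atlas[idx]
    tab <- sort(table(codes), decreasing = TRUE)
    nm <- label_table$name[match(as.integer(names(tab)), label_table$code)]
    nm[is.na(nm)] <- "unlabelled"
    out[[cl]] <- data.frame(cluster = cl,
                            cluster_voxels = length(idx),
                            label = as.character(nm),
                            voxels = as.integer(tab),
                            percent = round(100 * as.integer(tab) / length(idx), 1),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(cluster = integer(), cluster_voxels = integer(),
                      label = character(), voxels = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
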