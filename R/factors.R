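# Data-driven corroboration of the symptom domains: principal component
# analysis of the 10 MADRS items with oblique rotation of the retained
# components, and regression-method factor scores.

# Quartimin criterion and gradient (direct oblimin with delta = 0):
# f(L) = sum(L^2 * (L^2 %*% N)) / 4 with N = J - I.
vgQ_quartimin <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  M <- L2 %*% (matrix(1, k, k) - diag(k))
  list(f = sum(L2 * M) / 4, Gq = L * M)
}

# Oblique gradient projection rotation (Jennrich's GPA algorithm) of an
# unrotated loading matrix A under the quartimin criterion. Starting at the
# identity makes the result deterministic.
rotate_oblimin <- function(A, maxit = 1000L, tol = 1e-8) {
  k <- ncol(A)
  Tmat <- diag(k)
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- vgQ_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 0:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg <- vgQ_quartimin(L)
      if (vg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vg$f
    G <- -t(t(L) %*% vg$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat, f = f,
       iterations = iter)
}

# Promax variant offered as an alternative oblique rotation.
rotate_promax <- function(A, m = 4) {
  pr <- stats::promax(A, m = m)
  L <- unclass(pr$loadings)
  U <- pr$rotmat
  Phi <- solve(crossprod(U))
  list(loadings = L, Phi = Phi, Tmat = U)
}

#' Fit the PCA factor model of the MADRS items
#'
#' Principal component analysis on the item correlation matrix with a fixed
#' number of retained components, followed by oblique rotation (direct
#' oblimin with delta 0 by default, promax as an option). Factor scores use
#' the regression method: score coefficients `W = R^-1 S` where `S` is the
#' structure matrix, applied to standardized items. Each rotated factor is
#' sign-fixed so its largest-magnitude loading is positive, making the
#' solution deterministic.
#'
#' @param items Behaviour table with `item_1..item_10` columns or an n x 10
#'   matrix; n >= 2 and no constant column.
#' @param n_factors Number of retained components (default 5, at most 10).
#' @param rotation `"oblimin"` (default) or `"promax"`.
#' @return An object of class `factor_solution`: `loadings` (10 x k pattern
#'   matrix), `structure`, `factor_correlations` (k x k), `eigenvalues`
#'   (all 10, unrotated), `explained_variance_pct`,
#'   `cumulative_variance_pct`, `score_coefficients` (10 x k), `scores`
#'   (n x k), `rotation`.
#' @export
fit_factors <- function(items, n_factors = 5L,
                        rotation = c("oblimin", "promax")) {
  rotation <- match.arg(rotation)
  M <- if (is.data.frame(items)) as.matrix(items[, madrs_item_columns()])
       else as.matrix(items)
  stopifnot(ncol(M) == 10L)
  if (nrow(M) < 2L) stop_fmt("need at least 2 patients to fit factors")
  if (n_factors > 10L) stop_fmt("n_factors must be at most 10")
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0))
    stop_fmt("constant item column(s): %s",
             paste(colnames(M)[sds == 0], collapse = ", "))
  R <- stats::cor(M)
  e <- eigen(R, symmetric = TRUE)
  eigenvalues <- e$values
  k <- n_factors
  A <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eigenvalues[seq_len(k)]), k)
  rot <- switch(rotation,
                oblimin = rotate_oblimin(A),
                promax = rotate_promax(A))
  L <- rot$loadings
  Phi <- rot$Phi
  # sign convention: largest-magnitude loading per factor positive
  signs <- vapply(seq_len(k), function(j) {
    v <- L[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1L))
  L <- sweep(L, 2L, signs, `*`)
  Phi <- diag(signs, k) %*% Phi %*% diag(signs, k)
  S <- L %*% Phi
  W <- solve(R, S)
  Z <- scale(M)
  scores <- Z %*% W
  fac_names <- paste0("F", seq_len(k))
  dimnames(L) <- dimnames(S) <- dimnames(W) <-
    list(colnames(M) %||% madrs_item_columns(), fac_names)
  dimnames(Phi) <- list(fac_names, fac_names)
  colnames(scores) <- fac_names
  structure(
    list(loadings = L, structure = S, factor_correlations = Phi,
         eigenvalues = eigenvalues,
         explained_variance_pct = 100 * eigenvalues / 10,
         cumulative_variance_pct = cumsum(100 * eigenvalues / 10),
         score_coefficients = W, scores = scores,
         rotation = rotation, n_factors = k),
    class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d factors (%s rotation), cumulative variance at k: %.1f%%\n",
              x$n_factors, x$rotation,
              x$cumulative_variance_pct[x$n_factors]))
  print(round(x$loadings, 2))
  invisible(x)
}

#' Cumulative explained variance at k components
#'
#' Sum of the first k unrotated eigenvalues over the total variance (10 for
#' 10 standardized items), as a percentage.
#'
#' @param solution A [fit_factors()] result.
#' @param k Number of components, 0..10.
#' @return Cumulative percentage in `[0, 100]`.
#' @export
explained_variance_at <- function(solution, k) {
  stopifnot(inherits(solution, "factor_solution"), k >= 0, k <= 10)
  if (k == 0) return(0)
  sum(solution$eigenvalues[seq_len(k)]) / 10 * 100
}

#' Tucker congruence between two loading matrices
#'
#' Mean (over factors) of the maximum-congruence assignment between the
#' columns of `x` and `y`: factors are matched by enumerating all column
#' permutations and the absolute congruence
#' `|sum(a*b)| / sqrt(sum(a^2) sum(b^2))` is used, since oblique factor
#' solutions are defined only up to column order and sign.
#'
#' @param x,y Loading matrices with equal dimensions (at most 7 columns).
#' @return List with `mean_congruence`, the per-factor `congruence` under
#'   the best assignment, and the column `permutation` of `y`.
#' @export
tucker_congruence <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)), ncol(x) <= 7L)
  k <- ncol(x)
  cong <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  C <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cong(x[, i], y[, j])))
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1L, function(p) !anyDuplicated(p)), , drop = FALSE]
  vals <- apply(perms, 1L, function(p) mean(C[cbind(seq_len(k), p)]))
  best <- which.max(vals)
  p <- perms[best, ]
  list(mean_congruence = vals[best],
       congruence = C[cbind(seq_len(k), p)],
       permutation = as.integer(p))
}
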