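#' Construct a lesion mask object
#'
#' A lesion mask is one patient's binary 3D lesion map together with its
#' geometry: the voxel size in millimetres and the 4x4 voxel-to-world affine.
#' All masks entering a single analysis must share grid shape and affine.
#'
#' @param grid 3D array of 0/1 values (logical arrays are coerced).
#' @param voxel_size_mm Voxel edge lengths in mm; a scalar is recycled to
#'   three isotropic dimensions.
#' @param affine Optional 4x4 voxel-to-world transform; defaults to a pure
#'   scaling by the voxel size.
#' @param patient_id Identifier carried through to error messages and tables.
#' @return An object of class `lesion_mask` with fields `grid`, `affine`,
#'   `voxel_size_mm` and `patient_id`.
#' @export
lesion_mask <- function(grid, voxel_size_mm = c(1, 1, 1), affine = NULL,
                        patient_id = NA_character_) {
  if (length(dim(grid)) != 3L)
    stop_fmt("lesion mask must be a 3D volume, got %d dimension(s)",
             length(dim(grid)))
  if (is.logical(grid)) grid <- grid * 1L
  vals <- unique(as.vector(grid))
  if (!all(vals %in% c(0, 1)))
    stop_fmt("lesion mask values must be binary 0/1 (found %s)",
             paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "))
  storage.mode(grid) <- "integer"
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop_fmt("affine must be invertible")
  structure(
    list(grid = grid, affine = affine,
         voxel_size_mm = as.numeric(voxel_size_mm),
         patient_id = as.character(patient_id)),
    class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> patient %s: %s grid, %d lesioned voxels (%.2f cm^3)\n",
              x$patient_id, paste(dim(x$grid), collapse = "x"),
              sum(x$grid), lesion_volume_cm3(x)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$grid), dim(b$grid)) && max(abs(a$affine - b$affine)) < tol
}

check_shared_geometry <- function(masks) {
  ref <- masks[[1L]]
  bad <- vapply(masks, function(m) !same_geometry(ref, m), logical(1L))
  if (any(bad))
    stop_fmt("masks differ in grid shape or affine: patient(s) %s do not match %s",
             paste(vapply(masks[bad], `[[`, "", "patient_id"), collapse = ", "),
             ref$patient_id)
  invisible(TRUE)
}

#' Read a binary lesion mask from a NIfTI file
#'
#' Values above 0.5 are mapped to 1, all others to 0, so interpolated or
#' probabilistic masks are tolerated. Geometry (voxel size, affine) is
#' preserved.
#'
#' @param path Path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param patient_id Identifier; defaults to the file name without extension.
#' @return A [lesion_mask()].
#' @export
read_lesion_mask <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop_fmt("lesion mask file not found: %s", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop_fmt("cannot read NIfTI file %s: %s",
                                               path, conditionMessage(e)))
  arr <- as.array(img)
  d <- dim(arr)
  # tolerate trailing singleton dimensions (e.g. 4D with one volume)
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
    arr <- array(arr, d[1:3])
    d <- dim(arr)
  }
  if (length(d) != 3L)
    stop_fmt("%s is not a 3D volume (dims: %s)", path, paste(d, collapse = "x"))
  grid <- (arr > 0.5) * 1L
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_mask(grid,
              voxel_size_mm = RNifti::pixdim(img)[1:3],
              affine = unclass(RNifti::xform(img))[1:4, 1:4],
              patient_id = patient_id)
}

#' Write a lesion mask (or any 3D map) to a NIfTI file
#'
#' @param x A [lesion_mask()] or a 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm,affine Geometry used when `x` is a bare array.
#' @return The path, invisibly.
#' @export
write_lesion_mask <- function(x, path, voxel_size_mm = c(1, 1, 1),
                              affine = NULL) {
  if (inherits(x, "lesion_mask")) {
    arr <- x$grid; voxel_size_mm <- x$voxel_size_mm; affine <- x$affine
  } else {
    arr <- x
    if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
    if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  }
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- voxel_size_mm
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Lesion volume in cubic centimetres
#'
#' Lesioned voxel count times the voxel volume, converted from mm^3 to cm^3.
#'
#' @param mask A [lesion_mask()].
#' @return Scalar volume in cm^3.
#' @export
lesion_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$grid) * prod(mask$voxel_size_mm) / 1000
}

#' Lesion overlap map
#'
#' Voxel-wise count of patients whose lesion covers each voxel, summarizing
#' the spatial coverage of a cohort.
#'
#' @param masks List of [lesion_mask()] objects sharing geometry.
#' @return A list with `counts` (3D integer grid), `max_overlap`, and the
#'   shared geometry.
#' @export
overlap_map <- function(masks) {
  stopifnot(length(masks) >= 1L)
  check_shared_geometry(masks)
  counts <- Reduce(`+`, lapply(masks, `[[`, "grid"))
  storage.mode(counts) <- "integer"
  list(counts = counts, max_overlap = max(counts),
       voxel_size_mm = masks[[1L]]$voxel_size_mm,
       affine = masks[[1L]]$affine)
}

#' Assemble the patients-by-voxels lesion matrix
#'
#' Stacks binary masks into an `n_patients x n_voxels` design matrix keeping
#' only voxels lesioned in at least `min_overlap` patients (the minimum
#' lesion threshold ensuring sufficient lesion overlap for multivariate
#' mapping; five in the reference analysis). Retained voxels are ordered
#' lexicographically by 0-based (x, y, z) array coordinates.
#'
#' @param masks List of [lesion_mask()] objects sharing geometry.
#' @param min_overlap Minimum number of patients lesioned at a voxel for the
#'   voxel to enter the analysis.
#' @return An object of class `lesion_matrix` with fields `data` (n x v
#'   binary matrix), `voxel_index` (v x 3 integer matrix of 0-based
#'   coordinates), `overlap_counts`, `lesion_volumes` (cm^3 per patient),
#'   `patient_ids`, `grid_shape`, `voxel_size_mm`, `affine`, `min_overlap`.
#' @export
build_lesion_matrix <- function(masks, min_overlap = 5L) {
  stopifnot(length(masks) >= 1L, min_overlap >= 1L)
  check_shared_geometry(masks)
  ref <- masks[[1L]]
  counts <- Reduce(`+`, lapply(masks, `[[`, "grid"))
  keep <- which(counts >= min_overlap)
  coords <- arrayInd(keep, dim(counts))
  ord <- order(coords[, 1L], coords[, 2L], coords[, 3L])
  keep <- keep[ord]
  coords <- coords[ord, , drop = FALSE]
  v <- length(keep)
  n <- length(masks)
  X <- matrix(0L, n, v)
  for (i in seq_len(n)) X[i, ] <- masks[[i]]$grid[keep]
  structure(
    list(data = X,
         voxel_index = coords - 1L,
         overlap_counts = as.integer(counts[keep]),
         lesion_volumes = vapply(masks, lesion_volume_cm3, numeric(1L)),
         patient_ids = vapply(masks, `[[`, "", "patient_id"),
         grid_shape = dim(ref$grid),
         voxel_size_mm = ref$voxel_size_mm,
         affine = ref$affine,
         min_overlap = as.integer(min_overlap)),
    class = "lesion_matrix")
}

#' @export
print.lesion_matrix <- function(x, ...) {
  cat(sprintf("<lesion_matrix> %d patients x %d voxels (min overlap %d), grid %s\n",
              nrow(x$data), ncol(x$data), x$min_overlap,
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

# Embed a per-retained-voxel vector back into the full 3D grid
# (non-retained voxels get `fill`).
embed_in_grid <- function(values, lmat, fill = 0) {
  arr <- array(fill, lmat$grid_shape)
  idx <- lmat$voxel_index + 1L
  arr[cbind(idx[, 1L], idx[, 2L], idx[, 3L])] <- values
  arr
}
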