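# Subject exclusion, common-voxel masking, and feature-matrix assembly.
#
# Voxel ordering contract: masked voxels are enumerated in R's native raster
# (column-major) order — first axis fastest — via which(mask$array). Every
# weight vector and feature column in the package uses this ordering, so
# reconstructed maps are reproducible bit for bit. Infinite values are
# treated as NaN throughout: both are non-usable outputs of an upstream GLM.

.usable <- function(x) is.finite(x)   # FALSE for NA, NaN, +-Inf

.check_same_grid <- function(volumes) {
  if (!length(volumes)) stop("no volumes supplied")
  d0 <- dim(volumes[[1]])
  for (v in volumes)
    if (!identical(dim(v), d0)) stop("volumes do not share a grid")
  d0
}

#' Construct a brain mask
#'
#' @param arr Logical (or coercible) 3-D array; `TRUE` marks in-mask voxels.
#' @return A `brain_mask` object with fields `array`, `voxel_count`, and the
#'   linear indices of in-mask voxels in raster order (`indices`).
#' @export
brain_mask <- function(arr) {
  if (length(dim(arr)) != 3L) stop("mask must be a 3-D array")
  m <- array(as.logical(arr), dim(arr))
  if (anyNA(m)) stop("mask contains NA")
  structure(list(array = m, voxel_count = sum(m), indices = which(m),
                 ordering = "raster-column-major"),
            class = "brain_mask")
}

#' Default scope mask: voxels usable in at least half the subjects
#'
#' The subject-exclusion rule needs a denominator ("fraction of missing
#' voxels *of what*"). The package default scopes it to voxels that are
#' finite and nonzero in at least half the supplied volumes — a data-driven
#' stand-in for a standard brain mask that avoids diluting the fraction with
#' empty field-of-view.
#'
#' @param volumes List of 3-D arrays on a shared grid.
#' @return A [brain_mask()].
#' @export
default_scope_mask <- function(volumes) {
  d <- .check_same_grid(volumes)
  cnt <- array(0L, d)
  for (v in volumes) cnt <- cnt + (.usable(v) & v != 0)
  brain_mask(cnt >= length(volumes) / 2)
}

#' Exclude subjects with excessive missing voxels
#'
#' A subject is excluded iff the fraction of non-usable (NaN/NA/Inf) voxels
#' within the scope mask is strictly greater than `max_nan_fraction`
#' (default 0.15: the ">15% missing voxels" rule, so a subject at exactly
#' 15% is kept). Input order is preserved.
#'
#' @param volumes Named or unnamed list of 3-D arrays on one grid.
#' @param scope_mask A [brain_mask()]; default [default_scope_mask()] of the
#'   input volumes.
#' @param max_nan_fraction Exclusion threshold in `[0, 1]`.
#' @param ids Optional subject identifiers (default: names or indices).
#' @return List with `kept` and `excluded` id vectors and `report`, a
#'   `data.frame` (`subject_id`, `nan_fraction`, `kept`).
#' @export
exclude_subjects <- function(volumes, scope_mask = NULL,
                             max_nan_fraction = 0.15, ids = NULL) {
  .check_same_grid(volumes)
  stopifnot(max_nan_fraction >= 0, max_nan_fraction <= 1)
  if (is.null(scope_mask)) scope_mask <- default_scope_mask(volumes)
  stopifnot(inherits(scope_mask, "brain_mask"))
  if (!identical(dim(scope_mask$array), dim(volumes[[1]])))
    stop("scope mask grid does not match volumes")
  if (scope_mask$voxel_count == 0) stop("scope mask is empty")
  if (is.null(ids))
    ids <- if (!is.null(names(volumes))) names(volumes)
           else sprintf("sub-%03d", seq_along(volumes))
  frac <- vapply(volumes, function(v)
    sum(!.usable(v[scope_mask$indices])) / scope_mask$voxel_count, 0)
  keep <- frac <= max_nan_fraction
  list(kept = ids[keep], excluded = ids[!keep],
       report = data.frame(subject_id = ids, nan_fraction = unname(frac),
                           kept = unname(keep), stringsAsFactors = FALSE))
}

#' Build the common-voxel mask
#'
#' True exactly where the scope mask is true and every subject's value is
#' usable (finite): voxels with a NaN (or Inf) in any subject are removed, so
#' the downstream feature matrix is NaN-free by construction.
#'
#' @param volumes List of 3-D arrays for the *kept* subjects.
#' @param scope_mask A [brain_mask()]; default: all voxels.
#' @return A [brain_mask()]. Errors if the result is empty.
#' @export
build_common_mask <- function(volumes, scope_mask = NULL) {
  d <- .check_same_grid(volumes)
  ok <- if (is.null(scope_mask)) array(TRUE, d) else {
    stopifnot(inherits(scope_mask, "brain_mask"))
    if (!identical(dim(scope_mask$array), d))
      stop("scope mask grid does not match volumes")
    scope_mask$array
  }
  for (v in volumes) ok <- ok & .usable(v)
  if (!any(ok)) stop("empty mask: no voxel is usable in all subjects")
  brain_mask(ok)
}

#' Assemble the subjects-by-voxels feature matrix
#'
#' Row `i`, column `j` holds subject `i`'s value at the mask's `j`-th voxel
#' (raster order). Errors if any in-mask value is non-usable, which signals a
#' mask/volume mismatch.
#'
#' @param volumes List of 3-D arrays on the mask's grid.
#' @param mask A [brain_mask()], normally from [build_common_mask()] over the
#'   same subjects.
#' @param ids Optional subject identifiers.
#' @return A `feature_matrix`: list with `values` (n x V matrix),
#'   `subject_ids`, `mask`.
#' @export
assemble_features <- function(volumes, mask, ids = NULL) {
  d <- .check_same_grid(volumes)
  stopifnot(inherits(mask, "brain_mask"))
  if (!identical(dim(mask$array), d)) stop("mask grid does not match volumes")
  if (is.null(ids))
    ids <- if (!is.null(names(volumes))) names(volumes)
           else sprintf("sub-%03d", seq_along(volumes))
  X <- t(vapply(volumes, function(v) v[mask$indices],
                numeric(mask$voxel_count)))
  if (mask$voxel_count == 1L) X <- matrix(X, ncol = 1L)
  if (any(!.usable(X)))
    stop("NaN/Inf inside the mask: mask does not match these volumes")
  rownames(X) <- ids
  structure(list(values = X, subject_ids = ids, mask = mask),
            class = "feature_matrix")
}

#' Scatter a voxel vector back into a volume
#'
#' Inverse of the masking step: writes `values` at the mask's voxels (raster
#' order) and `fill` elsewhere.
#'
#' @param values Numeric vector of length `mask$voxel_count`.
#' @param mask A [brain_mask()].
#' @param fill Value for out-of-mask voxels (default 0).
#' @return A 3-D array on the mask's grid.
#' @export
vector_to_volume <- function(values, mask, fill = 0) {
  stopifnot(inherits(mask, "brain_mask"),
            length(values) == mask$voxel_count)
  vol <- array(fill, dim(mask$array))
  vol[mask$indices] <- values
  vol
}
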