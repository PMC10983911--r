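# Volume containers and NIfTI I/O.
#
# A volume is a light S3 wrapper around a 3D numeric array plus a 4x4 affine
# (voxel -> mm world transform). All volumes taking part in one analysis must
# live on a single grid: identical array dimensions and affines equal within
# a small tolerance. Mismatched grids are an error, never silently resampled.

AFFINE_TOL <- 1e-4

#' Create a labeled 3D volume
#'
#' @param data 3D numeric array of voxel values.
#' @param affine 4x4 voxel-to-world (mm) transform; must be invertible.
#' @param label Free-text identifier (subject/run/session/contrast).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(data, affine = diag(4), label = "volume") {
  data <- as_volume_array(data)
  affine <- check_affine(affine)
  structure(
    list(data = data, affine = affine, label = as.character(label)[1]),
    class = "labeled_volume"
  )
}

#' Create a binary brain mask
#'
#' @param data 3D array with values in `{0, 1}` (logical accepted); at least
#'   one voxel must be nonzero.
#' @inheritParams labeled_volume
#' @return An object of class `brain_mask` (also a `labeled_volume`).
#' @export
brain_mask <- function(data, affine = diag(4), label = "mask") {
  data <- as_volume_array(data)
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  if (!all(data %in% c(0, 1))) {
    abort("mask data must be binary (0/1)")
  }
  if (sum(data) < 1) abort("empty mask: at least one voxel must be nonzero")
  vol <- labeled_volume(data, affine, label)
  class(vol) <- c("brain_mask", class(vol))
  vol
}

as_volume_array <- function(data) {
  if (is.null(dim(data))) abort("volume data must be a 3D array")
  d <- dim(data)
  # accept a 4D array with a singleton trailing axis
  if (length(d) == 4 && d[4] == 1) {
    data <- array(data, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3) abort(sprintf("non-3D data: got %d dimensions", length(d)))
  if (any(d < 1)) abort("volume dimensions must be >= 1")
  # plain double array: strip any reader attributes
  array(as.double(data), dim = d)
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) abort("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps) abort("affine must be invertible")
  unname(affine)
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf(
    "<%s> '%s' %s voxels\n", class(x)[1], x$label,
    paste(dim(x$data), collapse = " x ")
  ))
  invisible(x)
}

#' Test whether two volumes share one grid
#'
#' Same array dimensions and affines equal within `1e-4` mm.
#' @param a,b `labeled_volume` (or `brain_mask`) objects.
#' @return Logical scalar.
#' @export
grid_compatible <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= AFFINE_TOL
}

check_grids <- function(a, b, what = "volumes") {
  if (!grid_compatible(a, b)) {
    abort(sprintf("grid mismatch: %s do not share shape/affine", what))
  }
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' Reads `.nii` / `.nii.gz` via RNifti. A 4D file with a singleton last axis
#' is squeezed to 3D; any other non-3D file is an error.
#'
#' @param path Path to a NIfTI file.
#' @param label Volume label; defaults to the file basename without extension.
#' @return A [labeled_volume()].
#' @export
read_volume <- function(path, label = NULL) {
  if (!file.exists(path)) abort(sprintf("missing file: %s", path))
  img <- RNifti::readNifti(path)
  if (is.null(label)) {
    label <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  labeled_volume(as.array(img), unclass(RNifti::xform(img)), label)
}

#' Read a binary mask volume
#'
#' @inheritParams read_volume
#' @return A [brain_mask()].
#' @export
read_mask <- function(path, label = NULL) {
  vol <- read_volume(path, label)
  brain_mask(vol$data, vol$affine, vol$label)
}

#' Write a volume to NIfTI
#'
#' @param vol A [labeled_volume()] or [brain_mask()].
#' @param path Output path (`.nii` or `.nii.gz`; gzip by extension).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  aff <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Assemble a measurement stack
#'
#' The unit of reliability analysis: `n` subjects each measured on `k >= 2`
#' occasions (runs or sessions), all maps aligned on one grid. `occasions` is
#' a list (length `k`) of lists (length `n`) of [labeled_volume()]s; subject
#' order must be identical across occasions.
#'
#' @param occasions List of `k` lists of `n` volumes.
#' @param subject_ids Character vector of `n` subject identifiers; defaults to
#'   `sub-01 ... sub-NN`.
#' @param occasion_labels Character vector of `k` occasion labels; defaults to
#'   `occ-1 ... occ-K`.
#' @return An object of class `measurement_stack`.
#' @export
measurement_stack <- function(occasions, subject_ids = NULL,
                              occasion_labels = NULL) {
  k <- length(occasions)
  if (k < 2) abort("need k >= 2 occasions")
  n <- length(occasions[[1]])
  if (n < 2) abort("need n >= 2 subjects")
  if (!all(vapply(occasions, length, 1L) == n)) {
    abort("all occasions must contain the same number of subjects")
  }
  ref <- occasions[[1]][[1]]
  for (occ in occasions) {
    for (vol in occ) check_grids(ref, vol, "stack volumes")
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%02d", seq_len(n))
  if (length(subject_ids) != n) abort("subject_ids must have length n")
  if (is.null(occasion_labels)) occasion_labels <- sprintf("occ-%d", seq_len(k))
  structure(
    list(
      occasions = occasions, subject_ids = as.character(subject_ids),
      occasion_labels = as.character(occasion_labels),
      n = n, k = k, grid = list(dim = dim(ref$data), affine = ref$affine)
    ),
    class = "measurement_stack"
  )
}

#' @export
print.measurement_stack <- function(x, ...) {
  cat(sprintf(
    "<measurement_stack> n = %d subjects x k = %d occasions, grid %s\n",
    x$n, x$k, paste(x$grid$dim, collapse = " x ")
  ))
  invisible(x)
}

#' Read a measurement stack from a path manifest
#'
#' The manifest is a TSV with columns `subject_id`, `occasion`, `path` — an
#' explicit, auditable ordered-paths contract. Subject order within each
#' occasion follows the manifest order of the first occasion.
#'
#' @param manifest Path to a manifest TSV, or a data frame with those columns.
#' @return A [measurement_stack()].
#' @export
read_measurement_stack <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  need <- c("subject_id", "occasion", "path")
  if (!all(need %in% names(manifest))) {
    abort("manifest needs columns subject_id, occasion, path")
  }
  occ_levels <- unique(manifest$occasion)
  subj_levels <- unique(manifest$subject_id)
  occasions <- purrr::map(occ_levels, function(occ) {
    rows <- manifest[manifest$occasion == occ, ]
    if (!identical(sort(rows$subject_id), sort(subj_levels))) {
      abort(sprintf("occasion '%s' does not cover every subject exactly once", occ))
    }
    rows <- rows[match(subj_levels, rows$subject_id), ]
    purrr::map2(rows$path, rows$subject_id, function(p, s) read_volume(p, s))
  })
  measurement_stack(occasions, subject_ids = subj_levels,
                    occasion_labels = as.character(occ_levels))
}

#' Flatten a masked stack into per-occasion subject x voxel matrices
#'
#' Column `j` of every matrix corresponds to the same voxel; columns follow
#' R's native (column-major) array order over the nonzero mask voxels, so the
#' ordering is a pure function of the mask.
#'
#' @param stack A [measurement_stack()].
#' @param mask A [brain_mask()] on the stack's grid.
#' @return A list with `matrices` (list of `k` matrices, each `n x V`),
#'   `voxels` (integer linear indices into the 3D array), `dim`, `affine`.
#' @export
stack_to_matrix <- function(stack, mask) {
  check_grids(list(data = array(0, stack$grid$dim), affine = stack$grid$affine),
              mask, "stack and mask")
  voxels <- which(mask$data != 0)
  if (length(voxels) == 0) abort("empty mask")
  matrices <- purrr::map(stack$occasions, function(occ) {
    vals <- vapply(occ, function(v) v$data[voxels], numeric(length(voxels)))
    if (length(voxels) == 1) matrix(vals, ncol = 1) else t(vals)
  })
  list(matrices = matrices, voxels = voxels,
       dim = stack$grid$dim, affine = stack$grid$affine)
}

#' Map masked voxel values back into a volume
#'
#' Inverse of the flattening used by [stack_to_matrix()]: values land at the
#' given linear voxel indices, everywhere else is `fill`.
#'
#' @param values Numeric vector, one value per voxel index.
#' @param voxels Integer linear indices (as returned by [stack_to_matrix()]).
#' @param dim 3-vector of array dimensions.
#' @param affine 4x4 affine.
#' @param label Volume label.
#' @param fill Background value (default `NaN`).
#' @return A [labeled_volume()].
#' @export
values_to_volume <- function(values, voxels, dim, affine, label = "volume",
                             fill = NaN) {
  stopifnot(length(values) == length(voxels))
  arr <- array(fill, dim = dim)
  arr[voxels] <- values
  labeled_volume(arr, affine, label)
}

#' Partition a mask by a reference map threshold
#'
#' Splits in-mask voxels into a suprathreshold set (reference strictly
#' greater than `threshold`) and a subthreshold set (reference strictly less
#' than `threshold`). Voxels exactly at the threshold belong to neither.
#'
#' @param reference A [labeled_volume()] (e.g. a meta-analytic z-map).
#' @param mask A [brain_mask()] on the same grid.
#' @param threshold Numeric threshold (e.g. `z = 3.1`).
#' @return A list with `supra` and `sub` [brain_mask()]s.
#' @export
partition_by_reference <- function(reference, mask, threshold) {
  check_grids(reference, mask, "reference and mask")
  supra <- (reference$data > threshold) & (mask$data != 0)
  sub <- (reference$data < threshold) & (mask$data != 0)
  list(
    supra = new_mask(supra, mask$affine, paste0(mask$label, "_supra")),
    sub = new_mask(sub, mask$affine, paste0(mask$label, "_sub"))
  )
}

# internal mask constructor that tolerates an empty support (a partition or a
# thresholded map may legitimately select no voxels; downstream summaries on
# an empty mask return NaN)
new_mask <- function(data, affine, label) {
  data <- as_volume_array(array(as.numeric(data != 0), dim = dim(data)))
  vol <- labeled_volume(data, affine, label)
  class(vol) <- c("brain_mask", class(vol))
  vol
}
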