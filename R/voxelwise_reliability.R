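# Voxelwise and ROI-level reliability maps.

#' Voxelwise ICC with variance components
#'
#' Applies the subject x occasion variance decomposition independently to
#' every in-mask voxel and returns the five aligned maps: ICC estimate, lower
#' and upper confidence bounds, MSBS and MSWS. Voxels outside the mask are
#' `NaN`; degenerate (zero-variance) voxels yield `NaN` estimates.
#'
#' The computation is vectorised over voxels but identical to running
#' [icc_scalar()] on each voxel's extracted `n x k` matrix.
#'
#' @param stack A [measurement_stack()].
#' @param mask A [brain_mask()] on the stack's grid.
#' @param icc_type One of `"icc_3"`, `"icc_2"`, `"icc_1"`.
#' @param alpha Two-sided error rate for the confidence bounds.
#' @return An object of class `reliability_maps`: five [labeled_volume()]s
#'   (`icc`, `lower`, `upper`, `msbs`, `msws`) plus `icc_type`, `alpha`, `n`,
#'   `k` and the analysis `mask`.
#' @export
voxelwise_icc <- function(stack, mask, icc_type = c("icc_3", "icc_2", "icc_1"),
                          alpha = 0.05) {
  icc_type <- match.arg(icc_type)
  flat <- stack_to_matrix(stack, mask)
  res <- icc_matrix_stack(flat$matrices, icc_type, alpha)
  vol <- function(values, what) {
    values_to_volume(values, flat$voxels, flat$dim, flat$affine,
                     label = paste0(icc_type, "_", what))
  }
  structure(
    list(
      icc = vol(res$estimate, "icc"), lower = vol(res$lower, "lb"),
      upper = vol(res$upper, "ub"), msbs = vol(res$msbs, "msbs"),
      msws = vol(res$msws, "msws"),
      icc_type = icc_type, alpha = alpha, n = stack$n, k = stack$k,
      mask = mask
    ),
    class = "reliability_maps"
  )
}

# shared by voxelwise_icc and the bootstrap: per-voxel ICC + bounds from a
# list of k n x V matrices
icc_matrix_stack <- function(matrices, icc_type, alpha) {
  ms <- ms_components(matrices)
  b <- icc_bounds(ms, icc_type, alpha)
  list(estimate = icc_point(ms, icc_type), lower = b$lower, upper = b$upper,
       msbs = ms$msbs, msws = ms$msws)
}

#' @export
print.reliability_maps <- function(x, ...) {
  med <- median_within_mask(x$icc, x$mask)
  cat(sprintf(
    "<reliability_maps> %s, n = %d, k = %d, grid %s\n  median in-mask ICC = %.4f\n",
    x$icc_type, x$n, x$k, paste(dim(x$icc$data), collapse = " x "), med
  ))
  invisible(x)
}

#' @rdname voxelwise_icc
#' @param x A `reliability_maps` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per in-mask voxel with the voxel index,
#'   ICC estimate, bounds and mean squares; `glance()` one summary row of
#'   in-mask medians.
#' @export
tidy.reliability_maps <- function(x, ...) {
  voxels <- which(x$mask$data != 0)
  tibble::tibble(
    voxel = voxels,
    icc = x$icc$data[voxels], lower = x$lower$data[voxels],
    upper = x$upper$data[voxels],
    msbs = x$msbs$data[voxels], msws = x$msws$data[voxels]
  )
}

#' @rdname voxelwise_icc
#' @export
glance.reliability_maps <- function(x, ...) {
  tibble::tibble(
    icc_type = x$icc_type, n = x$n, k = x$k,
    median_icc = median_within_mask(x$icc, x$mask),
    median_msbs = median_within_mask(x$msbs, x$mask),
    median_msws = median_within_mask(x$msws, x$mask),
    n_voxels = sum(x$mask$data != 0)
  )
}

#' Write the five reliability maps as NIfTI files
#'
#' Files are written as `<prefix>_icc`, `_lb`, `_ub`, `_msbs`, `_msws` with
#' extension `.nii.gz`. Out-of-mask voxels are `NaN` by default; `background
#' = "zero"` writes 0 instead for viewers that dislike NaN.
#'
#' @param maps A [voxelwise_icc()] result.
#' @param prefix Output path prefix.
#' @param background `"nan"` or `"zero"`.
#' @return Named character vector of the five paths, invisibly.
#' @export
write_reliability_maps <- function(maps, prefix, background = c("nan", "zero")) {
  background <- match.arg(background)
  suffixes <- c(icc = "_icc", lower = "_lb", upper = "_ub",
                msbs = "_msbs", msws = "_msws")
  paths <- character(0)
  for (nm in names(suffixes)) {
    vol <- maps[[nm]]
    if (background == "zero") {
      vol$data[!is.finite(vol$data)] <- 0
    }
    p <- paste0(prefix, suffixes[[nm]], ".nii.gz")
    write_volume(vol, p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Median of a map within a mask
#'
#' Median over in-mask voxels with finite values; `NaN` voxels are excluded,
#' and an empty selection returns `NaN`.
#'
#' @param map A [labeled_volume()].
#' @param mask A [brain_mask()] on the same grid.
#' @return Numeric scalar.
#' @export
median_within_mask <- function(map, mask) {
  check_grids(map, mask, "map and mask")
  vals <- map$data[mask$data != 0]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NaN)
  median(vals)
}

#' ROI-level ICC from an integer-labeled atlas
#'
#' For each atlas label, either the ROI-mean signal per subject/occasion is
#' fed to [icc_scalar()] (`strategy = "mean_series"`, the default) or the
#' median of the voxelwise ICC map across the ROI is taken
#' (`strategy = "voxelwise_median"`). Both readings of "ROI reliability" are
#' exposed because aggregated series and aggregated coefficients answer
#' subtly different questions.
#'
#' @param stack A [measurement_stack()].
#' @param atlas A [labeled_volume()] of non-negative integer labels
#'   (0 = background).
#' @param mask Optional [brain_mask()] restricting the analysis; defaults to
#'   all nonzero atlas voxels.
#' @param icc_type,alpha As in [voxelwise_icc()].
#' @param strategy `"mean_series"` or `"voxelwise_median"`.
#' @param roi_names Optional named character vector mapping label -> name.
#' @return A tibble with one row per ROI: `roi_label`, `roi_name`,
#'   `estimate`, `lower`, `upper`, `msbs`, `msws`, `voxel_count`.
#' @export
roi_icc <- function(stack, atlas, mask = NULL,
                    icc_type = c("icc_3", "icc_2", "icc_1"), alpha = 0.05,
                    strategy = c("mean_series", "voxelwise_median"),
                    roi_names = NULL) {
  icc_type <- match.arg(icc_type)
  strategy <- match.arg(strategy)
  if (any(atlas$data %% 1 != 0) || any(atlas$data < 0)) {
    abort("atlas must contain non-negative integer labels")
  }
  if (is.null(mask)) {
    mask <- new_mask(atlas$data > 0, atlas$affine, "atlas_support")
  }
  check_grids(atlas, mask, "atlas and mask")
  labels <- sort(unique(as.integer(atlas$data[atlas$data > 0])))
  vox_maps <- if (strategy == "voxelwise_median") {
    voxelwise_icc(stack, mask, icc_type, alpha)
  }
  rows <- purrr::map(labels, function(lab) {
    in_roi <- which(atlas$data == lab & mask$data != 0)
    name <- if (!is.null(roi_names) && as.character(lab) %in% names(roi_names)) {
      roi_names[[as.character(lab)]]
    } else {
      paste0("roi-", lab)
    }
    if (length(in_roi) == 0) {
      return(tibble::tibble(
        roi_label = lab, roi_name = name, estimate = NaN, lower = NaN,
        upper = NaN, msbs = NaN, msws = NaN, voxel_count = 0L
      ))
    }
    if (strategy == "mean_series") {
      series <- vapply(stack$occasions, function(occ) {
        vapply(occ, function(v) mean(v$data[in_roi]), numeric(1))
      }, numeric(stack$n))
      fit <- icc_scalar(series, icc_type, alpha)
      tibble::tibble(
        roi_label = lab, roi_name = name, estimate = fit$estimate,
        lower = fit$lower, upper = fit$upper,
        msbs = fit$decomposition$msbs, msws = fit$decomposition$msws,
        voxel_count = length(in_roi)
      )
    } else {
      med <- function(vol) {
        vals <- vol$data[in_roi]
        vals <- vals[is.finite(vals)]
        if (length(vals) == 0) NaN else median(vals)
      }
      tibble::tibble(
        roi_label = lab, roi_name = name, estimate = med(vox_maps$icc),
        lower = med(vox_maps$lower), upper = med(vox_maps$upper),
        msbs = med(vox_maps$msbs), msws = med(vox_maps$msws),
        voxel_count = length(in_roi)
      )
    }
  })
  dplyr::bind_rows(rows)
}
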