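# Model-level support: precision-weighted fixed-effects combination of
# run-level effect maps, and contrast design efficiency.

#' Pair an effect map with its variance map
#'
#' @param beta A [labeled_volume()] of effect estimates.
#' @param variance A [labeled_volume()] of estimate variances (>= 0) on the
#'   same grid.
#' @return An object of class `effect_pair`.
#' @export
effect_pair <- function(beta, variance) {
  check_grids(beta, variance, "beta and variance")
  if (any(variance$data < 0, na.rm = TRUE)) abort("variances must be >= 0")
  structure(list(beta = beta, variance = variance), class = "effect_pair")
}

#' Precision-weighted fixed-effects combination of runs
#'
#' Combines two or more run-level effect/variance map pairs voxelwise into a
#' session-level pair: `beta_fx = sum(beta_i / var_i) / sum(1 / var_i)` and
#' `var_fx = 1 / sum(1 / var_i)`. A voxel with zero or non-finite variance in
#' any run is `NaN` in the output.
#'
#' @param runs List of two or more [effect_pair()]s on one grid.
#' @return An [effect_pair()] with combined beta and variance.
#' @export
fixed_effects_combine <- function(runs) {
  if (length(runs) < 2) abort("need at least 2 runs")
  ref <- runs[[1]]
  for (r in runs[-1]) check_grids(ref$beta, r$beta, "run maps")
  bad <- Reduce(`|`, lapply(runs, function(r) {
    !is.finite(r$variance$data) | r$variance$data <= 0 | !is.finite(r$beta$data)
  }))
  precision <- Reduce(`+`, lapply(runs, function(r) 1 / r$variance$data))
  weighted <- Reduce(`+`, lapply(runs, function(r) r$beta$data / r$variance$data))
  beta_fx <- weighted / precision
  var_fx <- 1 / precision
  beta_fx[bad] <- NaN
  var_fx[bad] <- NaN
  effect_pair(
    labeled_volume(beta_fx, ref$beta$affine, "fixed_effects_beta"),
    labeled_volume(var_fx, ref$beta$affine, "fixed_effects_variance")
  )
}

#' Contrast efficiency of a design matrix
#'
#' `1 / (c' (X'X)^{-1} c)`: the (unscaled) precision with which the contrast
#' `c` is estimated under design `X`. Strictly positive; doubles under row
#' duplication (more scans), scales quadratically under column scaling.
#'
#' @param design Numeric `T x p` design matrix (time points x regressors),
#'   full column rank; a data frame is accepted.
#' @param contrast Length-`p` numeric contrast vector, not all zero.
#' @return Numeric scalar.
#' @examples
#' contrast_efficiency(diag(2), c(1, 0))  # 1
#' @export
contrast_efficiency <- function(design, contrast) {
  x <- as.matrix(design)
  contrast <- as.numeric(contrast)
  if (length(contrast) != ncol(x)) {
    abort("contrast length must match the number of design columns")
  }
  if (all(contrast == 0)) abort("contrast must not be all zero")
  xtx <- crossprod(x)
  if (qr(x)$rank < ncol(x)) abort("rank-deficient design matrix")
  as.numeric(1 / (contrast %*% solve(xtx, contrast)))
}

#' Read a design matrix from TSV
#'
#' Expects a header row of regressor names; all columns numeric.
#'
#' @param path TSV path.
#' @return Numeric matrix with column names.
#' @export
read_design_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as.matrix(df)
}
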