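# Two-way (subject x occasion) variance decomposition and the single-rater
# intraclass correlation family.
#
# For an n x k data unit (n subjects measured on k occasions) the crossed
# ANOVA with subjects random and occasions fixed gives
#   SS_subjects = k * sum_i (mbar_i - mbar)^2        MSBS = SS_subjects/(n-1)
#   SS_columns  = n * sum_j (mbar_j - mbar)^2        MSC  = SS_columns/(k-1)
#   SS_error    = SS_total - SS_subjects - SS_columns
#                                                    MSE  = SS_error/((n-1)(k-1))
# and the one-way pooled within-subject mean square
#   MSWS = (SS_total - SS_subjects) / (n(k-1)).
#
# ICC estimators (single measurement):
#   ICC(3,1) consistency: (MSBS - MSE) / (MSBS + (k-1) MSE)
#   ICC(2,1) agreement:   (MSBS - MSE) / (MSBS + (k-1) MSE + k (MSC - MSE)/n)
#   ICC(1)   one-way:     (MSBS - MSWS) / (MSBS + (k-1) MSWS)
# Degenerate 0/0 units are reported as NaN (no signal, not "no consistency");
# negative estimates are reported as computed, never floored.

ICC_TYPES <- c("icc_1", "icc_2", "icc_3")

# Vectorised mean-square engine. `matrices`: list of k matrices, each n x V
# (one column per analysis unit). Returns per-unit vectors. This single code
# path serves the scalar case (V = 1), the voxelwise maps and the bootstrap.
ms_components <- function(matrices) {
  k <- length(matrices)
  n <- nrow(matrices[[1]])
  if (n < 2 || k < 2) abort("degenerate input: need n >= 2 and k >= 2")
  total <- Reduce(`+`, matrices)                      # n x V subject sums
  sumsq <- Reduce(`+`, lapply(matrices, function(m) colSums(m^2)))
  occ_means <- do.call(rbind, lapply(matrices, colMeans)) # k x V
  grand <- colMeans(occ_means)
  subj_means <- total / k
  ss_total <- sumsq - n * k * grand^2
  ss_subj <- k * (colSums(subj_means^2) - n * grand^2)
  ss_col <- n * colSums(sweep(occ_means, 2, grand)^2)
  ss_err <- ss_total - ss_subj - ss_col
  # clamp tiny negative round-off
  ss_total <- pmax(ss_total, 0); ss_subj <- pmax(ss_subj, 0)
  ss_col <- pmax(ss_col, 0); ss_err <- pmax(ss_err, 0)
  list(
    n = n, k = k, grand_mean = unname(grand),
    msbs = unname(ss_subj) / (n - 1),
    msc = unname(ss_col) / (k - 1),
    mse = unname(ss_err) / ((n - 1) * (k - 1)),
    msws = unname(ss_total - ss_subj) / (n * (k - 1))
  )
}

icc_point <- function(ms, icc_type) {
  icc_type <- match.arg(icc_type, ICC_TYPES)
  k <- ms$k
  with(ms, switch(icc_type,
    icc_3 = (msbs - mse) / (msbs + (k - 1) * mse),
    icc_2 = (msbs - mse) / (msbs + (k - 1) * mse + k * (msc - mse) / n),
    icc_1 = (msbs - msws) / (msbs + (k - 1) * msws)
  ))
}

# F-statistic confidence bounds, vectorised over units. Consistency and
# one-way bounds follow the classical F-pivot; agreement bounds follow the
# Shrout-Fleiss interval with Satterthwaite degrees of freedom.
icc_bounds <- function(ms, icc_type, alpha = 0.05) {
  icc_type <- match.arg(icc_type, ICC_TYPES)
  stopifnot(alpha > 0, alpha < 1)
  n <- ms$n; k <- ms$k
  if (icc_type == "icc_3") {
    f <- ms$msbs / ms$mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else if (icc_type == "icc_1") {
    f <- ms$msbs / ms$msws
    df1 <- n - 1; df2 <- n * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else {
    icc <- icc_point(ms, "icc_2")
    fj <- ms$msc / ms$mse
    a <- k * icc * fj + n * (1 + (k - 1) * icc) - k * icc
    v <- (k - 1) * (n - 1) * a^2 /
      ((n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2)
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    denom <- k * ms$msc + (k * n - k - n) * ms$mse
    lower <- n * (ms$msbs - f_l * ms$mse) / (f_l * denom + n * ms$msbs)
    upper <- n * (f_u * ms$msbs - ms$mse) / (denom + n * f_u * ms$msbs)
  }
  bad <- !is.finite(lower) | !is.finite(upper)
  lower[bad] <- NaN
  upper[bad] <- NaN
  list(lower = lower, upper = upper)
}

#' Two-way variance decomposition of an n x k data unit
#'
#' Decomposes an `n` subjects by `k` occasions matrix into the ANOVA mean
#' squares used by the ICC family: between-subject (MSBS), occasion (MSC),
#' two-way residual (MSE), and the one-way pooled within-subject mean square
#' (MSWS).
#'
#' @param data Numeric matrix, `n >= 2` rows (subjects) by `k >= 2` columns
#'   (occasions), finite entries.
#' @return An object of class `variance_decomp` with fields `n`, `k`, `msbs`,
#'   `msws`, `msc`, `mse`, `grand_mean`.
#' @examples
#' decompose_variance(cbind(c(1, 3, 6, 9, 12), c(3, 9, 18, 27, 36)))
#' @export
decompose_variance <- function(data) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) abort("non-finite entries in data")
  if (nrow(data) < 2 || ncol(data) < 2) {
    abort("degenerate input: need n >= 2 subjects and k >= 2 occasions")
  }
  mats <- lapply(seq_len(ncol(data)), function(j) data[, j, drop = FALSE])
  ms <- ms_components(mats)
  structure(
    list(n = ms$n, k = ms$k, msbs = ms$msbs[1], msws = ms$msws[1],
         msc = ms$msc[1], mse = ms$mse[1], grand_mean = ms$grand_mean[1]),
    class = "variance_decomp"
  )
}

#' @export
print.variance_decomp <- function(x, ...) {
  cat(sprintf(
    "<variance_decomp> n = %d, k = %d\n  MSBS %.5g  MSWS %.5g  MSC %.5g  MSE %.5g\n",
    x$n, x$k, x$msbs, x$msws, x$msc, x$mse
  ))
  invisible(x)
}

#' ICC point estimate from a variance decomposition
#'
#' @param vd A [decompose_variance()] result.
#' @param icc_type One of `"icc_1"` (one-way random), `"icc_2"` (two-way
#'   agreement, ICC(2,1)), `"icc_3"` (two-way consistency, ICC(3,1)).
#' @return Numeric scalar; `NaN` when the denominator is zero.
#' @export
icc_from_decomposition <- function(vd, icc_type = c("icc_3", "icc_2", "icc_1")) {
  icc_type <- match.arg(icc_type)
  icc_point(vd, icc_type)
}

#' F-statistic confidence bounds for an ICC
#'
#' Consistency (`icc_3`) and one-way (`icc_1`) bounds use the classical
#' F-pivot on `MSBS/MSE` (resp. `MSBS/MSWS`); agreement (`icc_2`) bounds use
#' the Shrout-Fleiss interval with Satterthwaite degrees of freedom. Zero
#' error variance yields `(NaN, NaN)`.
#'
#' @inheritParams icc_from_decomposition
#' @param alpha Two-sided type-I error rate in (0, 1); 0.05 gives a 95% CI.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
confidence_bounds <- function(vd, icc_type = c("icc_3", "icc_2", "icc_1"),
                              alpha = 0.05) {
  icc_type <- match.arg(icc_type)
  b <- icc_bounds(vd, icc_type, alpha)
  c(lower = b$lower[1], upper = b$upper[1])
}

#' Scalar ICC with confidence bounds
#'
#' Convenience composition of [decompose_variance()],
#' [icc_from_decomposition()] and [confidence_bounds()].
#'
#' @inheritParams decompose_variance
#' @inheritParams confidence_bounds
#' @return An object of class `icc_fit` with `estimate`, `lower`, `upper`,
#'   `icc_type`, `alpha` and the underlying `variance_decomp`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' icc_scalar(cbind(c(1, 3, 6, 9, 12), c(3, 9, 18, 27, 36)))  # ICC(3,1) = 0.6
#' @export
icc_scalar <- function(data, icc_type = c("icc_3", "icc_2", "icc_1"),
                       alpha = 0.05) {
  icc_type <- match.arg(icc_type)
  vd <- decompose_variance(data)
  b <- confidence_bounds(vd, icc_type, alpha)
  structure(
    list(estimate = icc_from_decomposition(vd, icc_type),
         lower = unname(b["lower"]), upper = unname(b["upper"]),
         icc_type = icc_type, alpha = alpha, decomposition = vd),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(
    "<icc_fit> %s = %.4f [%.4f, %.4f] (alpha = %.2g, n = %d, k = %d)\n",
    x$icc_type, x$estimate, x$lower, x$upper, x$alpha,
    x$decomposition$n, x$decomposition$k
  ))
  invisible(x)
}

#' @rdname icc_scalar
#' @param x An `icc_fit` object.
#' @param ... Unused.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    icc_type = x$icc_type, estimate = x$estimate,
    conf.low = x$lower, conf.high = x$upper, alpha = x$alpha
  )
}

#' @rdname icc_scalar
#' @export
glance.icc_fit <- function(x, ...) {
  vd <- x$decomposition
  tibble::tibble(
    icc_type = x$icc_type, estimate = x$estimate,
    conf.low = x$lower, conf.high = x$upper,
    msbs = vd$msbs, msws = vd$msws, msc = vd$msc, mse = vd$mse,
    n = vd$n, k = vd$k
  )
}

#' @rdname decompose_variance
#' @param x A `variance_decomp` object.
#' @param ... Unused.
#' @export
tidy.variance_decomp <- function(x, ...) {
  tibble::tibble(
    term = c("msbs", "msws", "msc", "mse"),
    mean_square = c(x$msbs, x$msws, x$msc, x$mse),
    n = x$n, k = x$k
  )
}
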