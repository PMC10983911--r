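# Shared fixtures and independent oracles for the test suite.

# the printed two-occasion example: second occasion is three times the first
worked_example <- function() {
  cbind(c(1, 3, 6, 9, 12), c(3, 9, 18, 27, 36))
}

const_vol <- function(value, dim = c(2, 2, 2), affine = diag(4),
                      label = "vol") {
  labeled_volume(array(value, dim = dim), affine, label)
}

vec_vol <- function(values, dim, affine = diag(4), label = "vol") {
  labeled_volume(array(values, dim = dim), affine, label)
}

mask_all <- function(dim = c(2, 2, 2), affine = diag(4)) {
  brain_mask(array(1, dim = dim), affine, "mask")
}

# build a stack in which every voxel of subject i, occasion j carries
# data[i, j] — so each voxel's extracted matrix equals `data`
stack_from_matrix <- function(data, dim = c(2, 1, 1), affine = diag(4)) {
  n <- nrow(data)
  occasions <- lapply(seq_len(ncol(data)), function(j) {
    lapply(seq_len(n), function(i) const_vol(data[i, j], dim, affine))
  })
  measurement_stack(occasions)
}

# stack with fully random voxel data: occasion j, subject i holds draw (i, j)
random_stack <- function(n, k, dim, seed, affine = diag(4)) {
  set.seed(seed)
  occasions <- lapply(seq_len(k), function(j) {
    lapply(seq_len(n), function(i) {
      labeled_volume(array(rnorm(prod(dim)), dim = dim), affine,
                     sprintf("s%02d-o%d", i, j))
    })
  })
  measurement_stack(occasions)
}

# --- independent ANOVA oracle -------------------------------------------
# Mean squares via stats::aov on long-format data (a code path entirely
# separate from the package's vectorised engine), ICC and bounds via the
# textbook formulas written out directly.
oracle_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(n), times = k)),
    occ = factor(rep(seq_len(k), each = n))
  )
  two <- anova(aov(y ~ subj + occ, data = long))
  one <- anova(aov(y ~ subj, data = long))
  list(
    n = n, k = k,
    msbs = two["subj", "Mean Sq"],
    msc = two["occ", "Mean Sq"],
    mse = two["Residuals", "Mean Sq"],
    msws = one["Residuals", "Mean Sq"]
  )
}

oracle_icc <- function(mat, icc_type, alpha = 0.05) {
  ms <- oracle_ms(mat)
  n <- ms$n; k <- ms$k
  est <- switch(icc_type,
    icc_3 = (ms$msbs - ms$mse) / (ms$msbs + (k - 1) * ms$mse),
    icc_2 = (ms$msbs - ms$mse) /
      (ms$msbs + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n),
    icc_1 = (ms$msbs - ms$msws) / (ms$msbs + (k - 1) * ms$msws)
  )
  if (icc_type == "icc_3") {
    f <- ms$msbs / ms$mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1); upper <- (fu - 1) / (fu + k - 1)
  } else if (icc_type == "icc_1") {
    f <- ms$msbs / ms$msws
    fl <- f / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f * qf(1 - alpha / 2, n * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1); upper <- (fu - 1) / (fu + k - 1)
  } else {
    fj <- ms$msc / ms$mse
    a <- k * est * fj + n * (1 + (k - 1) * est) - k * est
    v <- (k - 1) * (n - 1) * a^2 /
      ((n - 1) * k^2 * est^2 * fj^2 + (n * (1 + (k - 1) * est) - k * est)^2)
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    denom <- k * ms$msc + (k * n - k - n) * ms$mse
    lower <- n * (ms$msbs - f_l * ms$mse) / (f_l * denom + n * ms$msbs)
    upper <- n * (f_u * ms$msbs - ms$mse) / (denom + n * f_u * ms$msbs)
  }
  list(estimate = est, lower = lower, upper = upper,
       msbs = ms$msbs, msws = ms$msws)
}

random_mask_pair <- function(nvox = 30) {
  a <- array(rbinom(nvox, 1, runif(1, 0.2, 0.8)), dim = c(nvox, 1, 1))
  b <- array(rbinom(nvox, 1, runif(1, 0.2, 0.8)), dim = c(nvox, 1, 1))
  a[1] <- 1; b[1] <- 1 # keep masks nonempty
  list(a = brain_mask(a), b = brain_mask(b))
}
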