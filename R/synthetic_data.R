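# Synthetic multi-subject, multi-occasion contrast maps with known variance
# components, plus matching reference maps and atlases, so every analysis in
# the package can be exercised with analytic ground truth and no downloads.
#
# The generative model per voxel v, subject i, occasion j is
#   y_ijv = mu + shift_j + b_iv + e_ijv,
#   b_iv ~ N(0, sigma2_between),  e_ijv ~ N(0, sigma2_within),
# independent across voxels by default (each voxel carries its own subject
# effect, so the per-voxel ground-truth consistency is
# sigma2_between / (sigma2_between + sigma2_within)). Inside a spherical
# "task-positive" target region the region's own variance pair applies,
# emulating the elevated reliability of strongly activated cortex.

#' Simulation configuration
#'
#' Defaults emulate a small-study test-retest design: 60 subjects, two
#' measurement occasions, a low-reliability background (ground-truth
#' consistency 0.2) and a spherical task-positive region of elevated
#' between-subject variance (ground-truth 0.5).
#'
#' @param shape Integer 3-vector of volume dimensions.
#' @param n_subjects Number of subjects (n >= 2).
#' @param k_occasions Number of occasions (k >= 2).
#' @param mu Grand mean signal.
#' @param sigma2_between Background subject-effect variance (>= 0).
#' @param sigma2_within Background residual variance (>= 0).
#' @param occasion_shift Additive per-occasion mean offset; occasion j gets
#'   `(j - 1) * occasion_shift`. Consistency (ICC(3,1)) is invariant to it,
#'   agreement (ICC(2,1)) is not.
#' @param target_center Integer 3-vector voxel center of the target sphere;
#'   defaults to the volume center. `NULL` radius 0 disables the region.
#' @param target_radius Sphere radius in voxels (>= 0; 0 = no region).
#' @param target_sigma2_between,target_sigma2_within Variance pair inside
#'   the target region.
#' @param shared_subject_effect If `TRUE`, one subject effect is shared by
#'   all voxels (spatially uniform individual differences) instead of
#'   independent per-voxel effects.
#' @param beta_variance_scale Positive scale for the constant variance maps
#'   attached to simulated effect pairs.
#' @param voxel_mm Isotropic voxel size used for the affine.
#' @param seed Integer seed; every simulated object is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(shape = c(10, 10, 10), n_subjects = 60,
                       k_occasions = 2, mu = 0,
                       sigma2_between = 0.25, sigma2_within = 1,
                       occasion_shift = 0,
                       target_center = NULL, target_radius = 3,
                       target_sigma2_between = 1, target_sigma2_within = 1,
                       shared_subject_effect = FALSE,
                       beta_variance_scale = 1,
                       voxel_mm = 2.4, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) abort("shape must be 3 positive integers")
  if (n_subjects < 2 || k_occasions < 2) abort("need n >= 2 and k >= 2")
  if (sigma2_between < 0 || sigma2_within < 0 ||
      target_sigma2_between < 0 || target_sigma2_within < 0) {
    abort("variances must be >= 0")
  }
  if (target_radius < 0) abort("target_radius must be >= 0")
  if (beta_variance_scale <= 0) abort("beta_variance_scale must be > 0")
  if (is.null(target_center)) target_center <- ceiling(shape / 2)
  target_center <- as.integer(target_center)
  if (any(target_center < 1) || any(target_center > shape)) {
    abort("target region must lie inside the volume")
  }
  structure(
    list(shape = shape, n_subjects = as.integer(n_subjects),
         k_occasions = as.integer(k_occasions), mu = mu,
         sigma2_between = sigma2_between, sigma2_within = sigma2_within,
         occasion_shift = occasion_shift, target_center = target_center,
         target_radius = target_radius,
         target_sigma2_between = target_sigma2_between,
         target_sigma2_within = target_sigma2_within,
         shared_subject_effect = isTRUE(shared_subject_effect),
         beta_variance_scale = beta_variance_scale,
         voxel_mm = voxel_mm, seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_affine <- function(config) {
  aff <- diag(c(rep(config$voxel_mm, 3), 1))
  aff[1:3, 4] <- -config$voxel_mm * config$shape / 2
  aff
}

region_array <- function(config) {
  shape <- config$shape
  if (config$target_radius <= 0) {
    return(array(FALSE, dim = shape))
  }
  idx <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                     z = seq_len(shape[3]))
  d2 <- (idx$x - config$target_center[1])^2 +
    (idx$y - config$target_center[2])^2 +
    (idx$z - config$target_center[3])^2
  array(d2 <= config$target_radius^2, dim = shape)
}

per_voxel_sigmas <- function(config) {
  region <- region_array(config)
  sb <- array(config$sigma2_between, dim = config$shape)
  se <- array(config$sigma2_within, dim = config$shape)
  sb[region] <- config$target_sigma2_between
  se[region] <- config$target_sigma2_within
  list(sb = sb, se = se, region = region)
}

#' Simulate a measurement stack with known ground truth
#'
#' @param config A [sim_config()].
#' @return A list with `stack` (a [measurement_stack()]), `truth` (a list
#'   with `icc_map`, the per-voxel ground-truth consistency
#'   `sigma_b^2 / (sigma_b^2 + sigma_e^2)`, and `region_mask`), and `mask`
#'   (all-voxel [brain_mask()]).
#' @examples
#' sim <- simulate_stack(sim_config(shape = c(4, 4, 4), n_subjects = 8))
#' sim$stack
#' @export
simulate_stack <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  aff <- sim_affine(config)
  sig <- per_voxel_sigmas(config)
  n <- config$n_subjects; k <- config$k_occasions
  nv <- prod(config$shape)
  set.seed(config$seed)
  sb_sd <- sqrt(as.vector(sig$sb))
  se_sd <- sqrt(as.vector(sig$se))
  b <- if (config$shared_subject_effect) {
    # one effect per subject, scaled to each voxel's between-subject sd
    outer(rnorm(n), sb_sd)
  } else {
    matrix(rnorm(n * nv), n, nv) * rep(sb_sd, each = n)
  }
  occasions <- lapply(seq_len(k), function(j) {
    shift <- (j - 1) * config$occasion_shift
    e <- matrix(rnorm(n * nv), n, nv) * rep(se_sd, each = n)
    y <- config$mu + shift + b + e
    lapply(seq_len(n), function(i) {
      labeled_volume(array(y[i, ], dim = config$shape), aff,
                     sprintf("sub-%03d_occ-%d", i, j))
    })
  })
  stack <- measurement_stack(
    occasions, subject_ids = sprintf("sub-%03d", seq_len(n)),
    occasion_labels = sprintf("occ-%d", seq_len(k))
  )
  truth_icc <- sig$sb / (sig$sb + sig$se)
  truth_icc[sig$sb + sig$se == 0] <- NaN
  list(
    stack = stack,
    truth = list(
      icc_map = labeled_volume(truth_icc, aff, "ground_truth_icc"),
      region_mask = new_mask(sig$region, aff, "target_region")
    ),
    mask = brain_mask(array(1, config$shape), aff, "mask")
  )
}

#' Simulate per-occasion group t-maps
#'
#' Generates subject maps under the configured variance model with a true
#' mean of `effect_d * sqrt(sigma_b^2 + sigma_e^2)` inside the target region
#' (zero outside), then computes a one-sample t-statistic over subjects per
#' voxel and occasion.
#'
#' @param config A [sim_config()].
#' @param effect_d True standardized effect size inside the target region.
#' @return List of `k` [labeled_volume()] t-maps.
#' @export
simulate_group_tmaps <- function(config, effect_d = 1) {
  stopifnot(inherits(config, "sim_config"))
  aff <- sim_affine(config)
  sig <- per_voxel_sigmas(config)
  n <- config$n_subjects
  nv <- prod(config$shape)
  total_sd <- sqrt(as.vector(sig$sb) + as.vector(sig$se))
  true_mean <- ifelse(as.vector(sig$region), effect_d * total_sd, 0)
  set.seed(config$seed)
  lapply(seq_len(config$k_occasions), function(j) {
    y <- matrix(rnorm(n * nv), n, nv) * rep(total_sd, each = n) +
      rep(true_mean, each = n)
    tstat <- colMeans(y) / (apply(y, 2, sd) / sqrt(n))
    labeled_volume(array(tstat, dim = config$shape), aff,
                   sprintf("group_tmap_occ-%d", j))
  })
}

#' Synthetic reference z-map and integer atlas
#'
#' The reference exceeds z = 3.1 exactly on the target region (value 5
#' inside, 0 outside), so a 3.1 partition recovers the region as the
#' suprathreshold mask. The atlas labels the target region 1 and its
#' complement 2 (0 = background is unused here since the mask covers the
#' volume).
#'
#' @param config A [sim_config()].
#' @return List with `reference` ([labeled_volume()]) and `atlas`
#'   ([labeled_volume()] of integer labels).
#' @export
make_reference_and_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  aff <- sim_affine(config)
  region <- region_array(config)
  reference <- array(0, dim = config$shape)
  reference[region] <- 5
  atlas <- array(2, dim = config$shape)
  atlas[region] <- 1
  list(
    reference = labeled_volume(reference, aff, "synthetic_reference_z"),
    atlas = labeled_volume(atlas, aff, "synthetic_atlas")
  )
}

#' Simulate constant-variance effect pairs per run
#'
#' Produces `n_runs` [effect_pair()]s whose beta maps follow the configured
#' variance model and whose variance maps are the constant
#' `sigma2_within * beta_variance_scale`, so the precision-weighted
#' combination has a closed form (the arithmetic mean with variance divided
#' by the run count).
#'
#' @param config A [sim_config()].
#' @param n_runs Number of runs (>= 2).
#' @return List of `n_runs` [effect_pair()]s.
#' @export
simulate_effect_pairs <- function(config, n_runs = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (n_runs < 2) abort("n_runs must be >= 2")
  aff <- sim_affine(config)
  nv <- prod(config$shape)
  sig <- per_voxel_sigmas(config)
  set.seed(config$seed)
  vconst <- config$sigma2_within * config$beta_variance_scale
  lapply(seq_len(n_runs), function(r) {
    beta <- rnorm(nv, sd = sqrt(as.vector(sig$sb) + as.vector(sig$se)))
    effect_pair(
      labeled_volume(array(beta, config$shape), aff, sprintf("run-%d_beta", r)),
      labeled_volume(array(vconst, config$shape), aff,
                     sprintf("run-%d_variance", r))
    )
  })
}

#' Write a complete synthetic fixture tree
#'
#' Writes the stack as `sub-XX/ses-YY/contrast.nii.gz`, plus `mask`,
#' `reference`, `atlas`, `ground_truth_icc` volumes and a `manifest.tsv`
#' (columns `subject_id`, `occasion`, `path`) mirroring the ordered-paths
#' input contract of [read_measurement_stack()].
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_fixture_tree <- function(config, dir) {
  sim <- simulate_stack(config)
  refs <- make_reference_and_atlas(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(seq_len(sim$stack$k), function(j) {
    occ <- sim$stack$occasion_labels[j]
    purrr::map_dfr(seq_len(sim$stack$n), function(i) {
      sid <- sim$stack$subject_ids[i]
      p <- file.path(dir, sid, gsub("occ-", "ses-", occ), "contrast.nii.gz")
      write_volume(sim$stack$occasions[[j]][[i]], p)
      tibble::tibble(subject_id = sid, occasion = occ, path = p)
    })
  })
  write_volume(sim$mask, file.path(dir, "mask.nii.gz"))
  write_volume(refs$reference, file.path(dir, "reference.nii.gz"))
  write_volume(refs$atlas, file.path(dir, "atlas.nii.gz"))
  write_volume(sim$truth$icc_map, file.path(dir, "ground_truth_icc.nii.gz"))
  manifest <- file.path(dir, "manifest.tsv")
  readr::write_tsv(rows, manifest)
  invisible(manifest)
}
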