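# The synthetic generator: known variance components, reference maps,
# atlases, and reproducibility.

test_that("config validation catches impossible settings", {
  expect_error(sim_config(shape = c(0, 2, 2)), "positive")
  expect_error(sim_config(n_subjects = 1), "n >= 2")
  expect_error(sim_config(sigma2_between = -1), ">= 0")
  expect_error(sim_config(target_center = c(99, 1, 1), target_radius = 1),
               "inside")
  expect_error(sim_config(beta_variance_scale = 0), "> 0")
})

test_that("zero within-subject variance gives a perfectly reliable stack", {
  sim <- simulate_stack(sim_config(
    shape = c(3, 3, 3), n_subjects = 10, sigma2_between = 1,
    sigma2_within = 0, target_radius = 0, seed = 1
  ))
  maps <- voxelwise_icc(sim$stack, sim$mask, "icc_3")
  expect_true(all(maps$icc$data == 1.0))
})

test_that("a null single-voxel simulation estimates ICC near zero", {
  sim <- simulate_stack(sim_config(
    shape = c(1, 1, 1), n_subjects = 5000, sigma2_between = 0,
    sigma2_within = 1, target_radius = 0, seed = 10
  ))
  maps <- voxelwise_icc(sim$stack, sim$mask, "icc_3")
  expect_lt(abs(maps$icc$data[1]), 0.05)
})

test_that("the ground-truth map matches the configured variance ratios", {
  cfg <- sim_config(shape = c(6, 6, 6), n_subjects = 10,
                    sigma2_between = 0.25, sigma2_within = 1,
                    target_radius = 2, target_sigma2_between = 1)
  sim <- simulate_stack(cfg)
  region <- sim$truth$region_mask$data != 0
  expect_true(all(sim$truth$icc_map$data[region] == 0.5))
  expect_true(all(sim$truth$icc_map$data[!region] == 0.2))
  expect_gt(sum(region), 0)
})

test_that("median estimates recover the ground truth at moderate n", {
  sim <- simulate_stack(sim_config(
    shape = c(6, 6, 6), n_subjects = 200, sigma2_between = 1,
    sigma2_within = 1, target_radius = 0, seed = 3
  ))
  maps <- voxelwise_icc(sim$stack, sim$mask, "icc_3")
  expect_equal(median_within_mask(maps$icc, sim$mask), 0.5, tolerance = 0.08)
})

test_that("occasion shifts leave consistency untouched and depress agreement", {
  base_args <- list(shape = c(4, 4, 4), n_subjects = 40, sigma2_between = 1,
                    sigma2_within = 1, target_radius = 0, seed = 6)
  sim0 <- simulate_stack(do.call(sim_config, c(base_args, occasion_shift = 0)))
  sim5 <- simulate_stack(do.call(sim_config, c(base_args, occasion_shift = 5)))
  m0 <- voxelwise_icc(sim0$stack, sim0$mask, "icc_3")
  m5 <- voxelwise_icc(sim5$stack, sim5$mask, "icc_3")
  expect_equal(m0$icc$data, m5$icc$data, tolerance = 1e-10)
  a0 <- voxelwise_icc(sim0$stack, sim0$mask, "icc_2")
  a5 <- voxelwise_icc(sim5$stack, sim5$mask, "icc_2")
  expect_lt(median_within_mask(a5$icc, sim5$mask),
            median_within_mask(a0$icc, sim0$mask))
})

test_that("generation is reproducible from the seed", {
  cfg <- sim_config(shape = c(3, 3, 3), n_subjects = 6, seed = 123)
  s1 <- simulate_stack(cfg)
  s2 <- simulate_stack(cfg)
  expect_identical(s1$stack$occasions[[1]][[1]]$data,
                   s2$stack$occasions[[1]][[1]]$data)
  t1 <- simulate_group_tmaps(cfg, effect_d = 1)
  t2 <- simulate_group_tmaps(cfg, effect_d = 1)
  expect_identical(t1[[2]]$data, t2[[2]]$data)
})

test_that("group t-maps carry the planted effect and only there", {
  cfg <- sim_config(shape = c(6, 6, 6), n_subjects = 60, sigma2_between = 1,
                    sigma2_within = 1, target_radius = 2, seed = 14)
  tmaps <- simulate_group_tmaps(cfg, effect_d = 1.2)
  region <- region <- simulate_stack(cfg)$truth$region_mask
  mask <- mask_all(c(6, 6, 6), tmaps[[1]]$affine)
  # region voxels survive a d >= .40 cut after conversion; background mostly not
  d <- t_to_cohens_d(tmaps[[1]], 60)
  hits <- binarize_map(d, mask, 0.4)
  expect_gt(mean(hits$data[region$data != 0]), 0.9)
  expect_lt(mean(hits$data[region$data == 0]), 0.1)
  # null effect: near-empty suprathreshold masks at z-like cut 3.1
  null_t <- simulate_group_tmaps(sim_config(
    shape = c(6, 6, 6), n_subjects = 60, target_radius = 0, seed = 15
  ), effect_d = 0)
  bin <- binarize_map(null_t[[1]], mask, 3.1)
  expect_lt(mean(bin$data), 0.02)
})

test_that("reference and atlas are consistent with the target region", {
  cfg <- sim_config(shape = c(5, 5, 5), n_subjects = 30, target_radius = 1,
                    target_sigma2_between = 4, seed = 21)
  refs <- make_reference_and_atlas(cfg)
  sim <- simulate_stack(cfg)
  parts <- partition_by_reference(refs$reference, sim$mask, 3.1)
  expect_equal(parts$supra$data, sim$truth$region_mask$data)
  expect_true(all(refs$atlas$data %in% c(1, 2)))
  tab <- roi_icc(sim$stack, refs$atlas)
  expect_gt(tab$estimate[tab$roi_label == 1], tab$estimate[tab$roi_label == 2])
})

test_that("effect pairs combine with the closed-form variance", {
  cfg <- sim_config(shape = c(3, 3, 3), n_subjects = 10,
                    beta_variance_scale = 2, sigma2_within = 1, seed = 33)
  runs <- simulate_effect_pairs(cfg, n_runs = 2)
  fx <- fixed_effects_combine(runs)
  expect_equal(unique(as.vector(fx$variance$data)), 2 / 2) # sigma2 * scale / k
  expect_equal(fx$beta$data, (runs[[1]]$beta$data + runs[[2]]$beta$data) / 2,
               tolerance = 1e-12)
})

test_that("parameter recovery holds across seeds for three ground truths", {
  # scaled-down companion of the acceptance check: 5 seeds, small volume
  truths <- c(0.2, 0.5, 0.8)
  sigmas_b <- truths / (1 - truths) # sigma_e^2 = 1
  for (ti in seq_along(truths)) {
    meds <- vapply(1:5, function(s) {
      sim <- simulate_stack(sim_config(
        shape = c(4, 4, 4), n_subjects = 200, sigma2_between = sigmas_b[ti],
        sigma2_within = 1, target_radius = 0, seed = 100 + s
      ))
      maps <- voxelwise_icc(sim$stack, sim$mask, "icc_3")
      median_within_mask(maps$icc, sim$mask)
    }, numeric(1))
    expect_equal(mean(meds), truths[ti], tolerance = 0.04)
  }
})
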