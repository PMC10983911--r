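# Voxelwise maps, in-mask medians and ROI-level reliability.

test_that("a stack replicating the worked example yields a constant 0.60 map", {
  stack <- stack_from_matrix(worked_example(), dim = c(2, 1, 1))
  mask <- mask_all(c(2, 1, 1))
  maps <- voxelwise_icc(stack, mask, "icc_3")
  vals <- maps$icc$data[mask$data != 0]
  expect_equal(vals, rep(0.6, 2), tolerance = 1e-12)
  expect_equal(maps$msbs$data[1], 157.6, tolerance = 1e-10)
  expect_equal(maps$msws$data[1], 108.4, tolerance = 1e-10)
  expect_identical(maps$n, 5L)
})

test_that("voxelwise maps equal the scalar fit voxel by voxel", {
  stack <- random_stack(n = 9, k = 3, dim = c(4, 4, 3), seed = 31)
  mask <- mask_all(c(4, 4, 3))
  for (type in c("icc_3", "icc_2", "icc_1")) {
    maps <- voxelwise_icc(stack, mask, type)
    flat <- stack_to_matrix(stack, mask)
    set.seed(17)
    for (j in sample(length(flat$voxels), 25)) {
      unit <- vapply(flat$matrices, function(m) m[, j], numeric(9))
      fit <- icc_scalar(unit, type)
      v <- flat$voxels[j]
      expect_equal(maps$icc$data[v], fit$estimate, tolerance = 1e-12)
      expect_equal(maps$lower$data[v], fit$lower, tolerance = 1e-12)
      expect_equal(maps$upper$data[v], fit$upper, tolerance = 1e-12)
      expect_equal(maps$msbs$data[v], fit$decomposition$msbs, tolerance = 1e-12)
      expect_equal(maps$msws$data[v], fit$decomposition$msws, tolerance = 1e-12)
    }
  }
})

test_that("a degenerate voxel yields NaN without disturbing its neighbours", {
  stack <- random_stack(n = 6, k = 2, dim = c(3, 1, 1), seed = 3)
  # voxel 2 constant across all subjects and occasions
  for (j in 1:2) for (i in 1:6) stack$occasions[[j]][[i]]$data[2] <- 1.5
  maps <- voxelwise_icc(stack, mask_all(c(3, 1, 1)))
  expect_true(is.nan(maps$icc$data[2]))
  expect_false(anyNA(maps$icc$data[c(1, 3)]))
  # out-of-mask voxels are NaN
  sel <- array(c(1, 0, 1), c(3, 1, 1))
  maps2 <- voxelwise_icc(stack, brain_mask(sel))
  expect_true(is.nan(maps2$icc$data[2]))
})

test_that("maps are invariant to a consistent permutation of subjects", {
  stack <- random_stack(n = 8, k = 2, dim = c(3, 3, 1), seed = 12)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  permuted <- measurement_stack(
    lapply(stack$occasions, function(occ) occ[perm]),
    subject_ids = stack$subject_ids[perm]
  )
  mask <- mask_all(c(3, 3, 1))
  m1 <- voxelwise_icc(stack, mask)
  m2 <- voxelwise_icc(permuted, mask)
  expect_equal(m1$icc$data, m2$icc$data, tolerance = 1e-12)
  expect_equal(m1$msbs$data, m2$msbs$data, tolerance = 1e-12)
})

test_that("median_within_mask follows the NaN-exclusion contract", {
  mask <- mask_all(c(3, 1, 1))
  expect_equal(median_within_mask(const_vol(0.3, c(3, 1, 1)), mask), 0.3)
  expect_equal(median_within_mask(vec_vol(c(0.1, 0.2, 0.9), c(3, 1, 1)), mask), 0.2)
  expect_equal(median_within_mask(vec_vol(c(0.1, NaN, 0.9), c(3, 1, 1)), mask), 0.5)
  expect_true(is.nan(median_within_mask(vec_vol(rep(NaN, 3), c(3, 1, 1)), mask)))
})

test_that("simulated stack recovers its ground-truth map median", {
  sim <- simulate_stack(sim_config(
    shape = c(20, 20, 20), n_subjects = 40, sigma2_between = 1,
    sigma2_within = 1, target_radius = 0, seed = 99
  ))
  maps <- voxelwise_icc(sim$stack, sim$mask, "icc_3")
  expect_equal(median_within_mask(maps$icc, sim$mask), 0.5, tolerance = 0.08)
})

test_that("the task-positive region shows higher median reliability", {
  sim <- simulate_stack(sim_config(
    shape = c(8, 8, 8), n_subjects = 50, sigma2_between = 0.25,
    sigma2_within = 1, target_radius = 2, target_sigma2_between = 1,
    seed = 4
  ))
  refs <- make_reference_and_atlas(sim_config(
    shape = c(8, 8, 8), n_subjects = 50, target_radius = 2, seed = 4
  ))
  parts <- partition_by_reference(refs$reference, sim$mask, 3.1)
  expect_equal(parts$supra$data, sim$truth$region_mask$data)
  maps <- voxelwise_icc(sim$stack, sim$mask)
  expect_gt(median_within_mask(maps$icc, parts$supra),
            median_within_mask(maps$icc, parts$sub))
})

test_that("ROI mean-series reliability decomposes over disjoint ROIs", {
  sim <- simulate_stack(sim_config(shape = c(6, 6, 6), n_subjects = 24,
                                   target_radius = 2, seed = 8))
  refs <- make_reference_and_atlas(sim_config(shape = c(6, 6, 6),
                                              n_subjects = 24,
                                              target_radius = 2, seed = 8))
  tab <- roi_icc(sim$stack, refs$atlas, icc_type = "icc_3")
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$roi_label, c(1L, 2L))
  # each row equals icc_scalar on that ROI's mean series
  for (lab in 1:2) {
    in_roi <- which(refs$atlas$data == lab)
    series <- vapply(sim$stack$occasions, function(occ) {
      vapply(occ, function(v) mean(v$data[in_roi]), numeric(1))
    }, numeric(sim$stack$n))
    fit <- icc_scalar(series, "icc_3")
    expect_equal(tab$estimate[tab$roi_label == lab], fit$estimate,
                 tolerance = 1e-12)
    expect_equal(tab$voxel_count[tab$roi_label == lab], length(in_roi))
  }
})

test_that("an ROI of one voxel matches the voxelwise map at that voxel", {
  stack <- random_stack(n = 7, k = 2, dim = c(3, 1, 1), seed = 23)
  atlas <- vec_vol(c(1, 0, 0), c(3, 1, 1), label = "atlas")
  mask <- mask_all(c(3, 1, 1))
  tab <- roi_icc(stack, atlas, mask = mask)
  maps <- voxelwise_icc(stack, mask)
  expect_equal(tab$estimate[1], maps$icc$data[1], tolerance = 1e-12)
  expect_equal(tab$lower[1], maps$lower$data[1], tolerance = 1e-12)
})

test_that("roi_icc exposes the aggregated-voxelwise alternative and NaN rows", {
  stack <- random_stack(n = 6, k = 2, dim = c(4, 1, 1), seed = 44)
  atlas <- vec_vol(c(1, 1, 0, 2), c(4, 1, 1), label = "atlas")
  sel <- array(c(1, 1, 1, 0), c(4, 1, 1)) # label 2 has no in-mask voxel
  mask <- brain_mask(sel)
  tab <- roi_icc(stack, atlas, mask = mask, strategy = "voxelwise_median")
  maps <- voxelwise_icc(stack, mask)
  expect_equal(tab$estimate[1], median(maps$icc$data[1:2]), tolerance = 1e-12)
  expect_true(is.nan(tab$estimate[tab$roi_label == 2]))
  expect_identical(tab$voxel_count[tab$roi_label == 2], 0L)
})

test_that("the five maps are written with matching grids and background option", {
  stack <- random_stack(n = 5, k = 2, dim = c(3, 3, 2), seed = 6)
  sel <- array(1, c(3, 3, 2)); sel[1, 1, 1] <- 0
  mask <- brain_mask(sel)
  maps <- voxelwise_icc(stack, mask)
  dir <- withr::local_tempdir()
  paths <- write_reliability_maps(maps, file.path(dir, "out"))
  expect_identical(unname(basename(paths)),
                   c("out_icc.nii.gz", "out_lb.nii.gz", "out_ub.nii.gz",
                     "out_msbs.nii.gz", "out_msws.nii.gz"))
  back <- read_volume(paths[["icc"]])
  expect_true(grid_compatible(back, maps$icc))
  expect_true(is.nan(back$data[1, 1, 1]))
  write_reliability_maps(maps, file.path(dir, "zero"), background = "zero")
  backz <- read_volume(file.path(dir, "zero_icc.nii.gz"))
  expect_identical(backz$data[1, 1, 1], 0)
})
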