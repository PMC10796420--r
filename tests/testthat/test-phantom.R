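test_that("zero binding and zero noise give identical pre/post pairs", {
  ph <- generate_phantom_pair(small_config(), seed = 5)
  expect_identical(ph$pre$voxels, ph$post$voxels)
  expect_identical(unname(ph$truth), integer(5))
})

test_that("flipped-voxel truth matches the direct voxel-difference count", {
  cfg <- narrowed_config(binding_fraction = c(R1 = 0.5, R3 = 0.2))
  ph <- generate_phantom_pair(cfg, seed = 9)
  diff_idx <- which(ph$pre$voxels != ph$post$voxels)
  expect_identical(length(diff_idx), as.integer(sum(ph$truth)))
  # every flipped voxel crosses any threshold strictly between the modes
  for (thr in c(25, 60, 95)) {
    expect_true(all(ph$pre$voxels[diff_idx] > thr))
    expect_true(all(ph$post$voxels[diff_idx] < thr))
  }
  # flips land in the right slices
  part <- partition_regions(ph$landmarks, n_slices(ph$pre))
  sl <- arrayInd(diff_idx, dim(ph$pre$voxels))[, 3] - 1L
  expect_identical(as.integer(table(factor(part$labels[sl + 1],
                                           levels = paste0("R", 1:5)))),
                   unname(ph$truth))
})

test_that("phantoms are a pure function of (config, seed)", {
  cfg <- narrowed_config(binding_fraction = c(R1 = 0.4), noise_sigma = 2)
  a <- generate_phantom_pair(cfg, seed = 21)
  b <- generate_phantom_pair(cfg, seed = 21)
  expect_identical(a$pre$voxels, b$pre$voxels)
  expect_identical(a$post$voxels, b$post$voxels)
  c <- generate_phantom_pair(cfg, seed = 22)
  expect_false(identical(a$post$voxels, c$post$voxels))
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(lumen_radius = 30), "exceeds grid bounds")
  expect_error(small_config(binding_fraction = c(R1 = 1.2)), "\\[0, 1\\]")
  expect_error(small_config(plaque_narrowing = c(R2 = 1)), "\\[0, 1\\)")
  expect_error(phantom_config(grid_shape = c(24, 24, 16), lumen_intensity = 10,
                              background_intensity = 20), "exceed")
})

test_that("cohort respects side, arm and week design constraints", {
  des <- cohort_design(n_animals = c(2, 2, 2, 2), weeks = c(10, 15, 30))
  co <- generate_cohort(des, small_config(), seed = 7)
  tr <- co$truth
  expect_true(all(tr$truth_count[tr$side == "LCCA"] == 0))
  expect_true(all(tr$truth_count[tr$probe == "IgG-MPIO"] == 0))
  expect_true(all(tr$truth_count[tr$treatment == "statin" &
                                   tr$probe == "DT-MPIO"] == 0))
  expect_true(all(tr$truth_count[tr$region == "R4"] == 0))
  # untreated DT-MPIO binding grows along the configured monotone trajectory
  r1 <- tr[tr$probe == "DT-MPIO" & tr$treatment == "none" &
             tr$side == "RCCA" & tr$region == "R1", ]
  m <- tapply(r1$truth_count, r1$week, mean)
  expect_gt(m[["30"]], m[["15"]])
  expect_identical(m[["10"]], 0)
})

test_that("the whole cohort is deterministic in the master seed", {
  des <- cohort_design(n_animals = c(1, 1, 1, 1), weeks = c(10, 30))
  a <- generate_cohort(des, small_config(), seed = 3)
  b <- generate_cohort(des, small_config(), seed = 3)
  expect_identical(a$truth, b$truth)
  expect_identical(a$histology, b$histology)
  expect_identical(a$animals[[1]]$scans[[1]]$RCCA$post$voxels,
                   b$animals[[1]]$scans[[1]]$RCCA$post$voxels)
})
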