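test_that("NIfTI round-trip preserves voxels and voxel size exactly", {
  set.seed(11)
  v <- mra_volume(array(runif(16 * 16 * 8) * 500, c(16, 16, 8)),
                  voxel_size = c(0.09, 0.09, 0.16),
                  meta = list(animal_id = "A1", side = "RCCA"))
  path <- file.path(tempdir(), "rt.nii.gz")
  write_volume(v, path)
  r <- read_volume(path, meta = v$meta)
  expect_identical(dim(r$voxels), dim(v$voxels))
  expect_identical(as.numeric(r$voxels), as.numeric(v$voxels))
  expect_equal(r$voxel_size, v$voxel_size, tolerance = 1e-6)
})

test_that("TIFF stacks round-trip at single precision with page = slice", {
  set.seed(12)
  v <- mra_volume(array(runif(16 * 16 * 16), c(16, 16, 16)))
  path <- file.path(tempdir(), "rt.tif")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(n_slices(r), 16L)
  expect_equal(as.numeric(r$voxels), as.numeric(v$voxels), tolerance = 1e-6)
  # absolute intensities beyond the unit range have no TIFF representation
  big <- mra_volume(array(100, c(4, 4, 4)))
  expect_error(write_volume(big, path), "unit-range")
})

test_that("degenerate volumes and unwritable paths are rejected", {
  expect_error(mra_volume(array(1, c(5, 5, 1))), "at least 2 slices")
  expect_error(mra_volume(array(-1, c(4, 4, 4))), ">= 0")
  expect_error(mra_volume(array(NA_real_, c(4, 4, 4))), "finite")
  v <- mra_volume(array(1, c(4, 4, 4)))
  expect_error(write_volume(v, "/nonexistent-dir/x.nii"), "not writable")
  expect_error(read_volume(file.path(tempdir(), "missing.nii")),
               "does not exist")
  expect_error(read_volume(file.path(tempdir(), "odd.xyz")))
})

test_that("realignment matches the explicit permutation and reversal oracles", {
  # labelled grid: value encodes the (i, j, k) coordinate uniquely
  g <- array(0, c(3, 4, 5))
  for (i in 1:3) for (j in 1:4) for (k in 1:5)
    g[i, j, k] <- 100 * i + 10 * j + k
  # axis permutation: former first axis becomes last
  v1 <- mra_volume(g, slice_axis = 1L, voxel_size = c(0.2, 0.3, 0.4))
  r1 <- realign_craniocaudal(v1)
  expect_identical(dim(r1$voxels), c(4L, 5L, 3L))
  expect_equal(r1$voxel_size, c(0.3, 0.4, 0.2))
  for (i in 1:3) for (j in 1:4) for (k in 1:5)
    expect_identical(r1$voxels[j, k, i], g[i, j, k])
  # slice-order reversal: slice k of output = slice n-1-k of input
  v2 <- mra_volume(g, slice_axis = 3L, slice_direction = -1L)
  r2 <- realign_craniocaudal(v2)
  for (k in 1:5)
    expect_identical(r2$voxels[, , k], g[, , 5 + 1 - k])
})

test_that("realignment is idempotent, intensity-preserving, identity when aligned", {
  set.seed(13)
  v <- mra_volume(array(runif(60), c(3, 4, 5)), slice_axis = 2L,
                  slice_direction = -1L)
  r <- realign_craniocaudal(v)
  expect_identical(realign_craniocaudal(r)$voxels, r$voxels)
  expect_identical(sort(as.numeric(r$voxels)), sort(as.numeric(v$voxels)))
  aligned <- mra_volume(array(runif(60), c(3, 4, 5)))
  expect_identical(realign_craniocaudal(aligned)$voxels, aligned$voxels)
})

test_that("landmark constructor enforces ordering and YAML sidecars round-trip", {
  expect_error(landmarks(10, 5, 20, 30), "branch < cuff_proximal")
  expect_error(landmarks(0, 10, 9, 30), "branch < cuff_proximal")
  expect_error(landmarks(-1, 5, 9, 12))
  lm <- landmarks(0, 30, 45, 63)
  path <- file.path(tempdir(), "lm.yaml")
  write_landmarks(lm, path, meta = list(animal_id = "A1", side = "RCCA",
                                        week = 30))
  r <- read_landmarks(path)
  expect_identical(unclass(r)[1:4], unclass(lm)[1:4])
  expect_identical(attr(r, "meta")$animal_id, "A1")
})
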