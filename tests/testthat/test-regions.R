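test_that("the worked 64-slice partition is reproduced exactly", {
  part <- partition_regions(landmarks(0, 30, 45, 63), 64)
  expect_identical(region_slices(part, "R1"), 0:9)
  expect_identical(region_slices(part, "R2"), 10:19)
  expect_identical(region_slices(part, "R3"), 20:29)
  expect_identical(region_slices(part, "R4"), 30:45)
  expect_identical(region_slices(part, "R5"), 46:63)
})

test_that("three-way split remainders go to the most proximal regions", {
  # span of 10 slices -> sizes (4, 3, 3)
  part <- partition_regions(landmarks(0, 10, 12, 20), 21)
  sizes <- vapply(paste0("R", 1:3), function(r)
    length(region_slices(part, r)), 1L)
  expect_identical(unname(sizes), c(4L, 3L, 3L))
  # span of 11 -> (4, 4, 3)
  part2 <- partition_regions(landmarks(0, 11, 12, 20), 21)
  sizes2 <- vapply(paste0("R", 1:3), function(r)
    length(region_slices(part2, r)), 1L)
  expect_identical(unname(sizes2), c(4L, 4L, 3L))
})

test_that("random landmark tuples always yield an exact partition", {
  set.seed(91)
  for (i in 1:100) {
    n <- sample(16:80, 1)
    lm <- random_landmark_tuple(n)
    part <- partition_regions(lm, n)
    lab <- part$labels
    span <- (lm$branch:lm$bifurcation) + 1
    expect_true(all(lab[span] %in% paste0("R", 1:5)))
    expect_true(all(lab[-span] == "outside"))
    sizes <- vapply(paste0("R", 1:3), function(r)
      length(region_slices(part, r)), 1L)
    expect_lte(abs(sizes[1] - sizes[2]), 1L)
    expect_lte(abs(sizes[2] - sizes[3]), 1L)
    # R1 is adjacent to the branch, R5 ends at the bifurcation
    expect_identical(min(region_slices(part, "R1")), lm$branch)
    expect_identical(max(region_slices(part, "R5")), lm$bifurcation)
    expect_identical(range(region_slices(part, "R4")),
                     c(lm$cuff_proximal, lm$cuff_distal))
  }
})

test_that("degenerate landmark spans are rejected", {
  expect_error(partition_regions(landmarks(0, 2, 5, 10), 16), "at least 3")
  expect_error(partition_regions(landmarks(0, 10, 12, 20), 15), "exceed")
})

test_that("region AUC differences follow the per-slice subtraction oracle", {
  part <- partition_regions(landmarks(0, 9, 10, 11), 12)
  # R1 covers slices 0-2 with a one-slice difference of 2
  pre <- area_curve(c(10, 12, 14, rep(9, 9)))
  post <- area_curve(c(8, 12, 14, rep(9, 9)))
  rs <- delta_auc(pre, post, part, "R1")
  expect_identical(rs$auc_pre, 36)
  expect_identical(rs$auc_post, 34)
  expect_identical(rs$delta_auc, 2)
  expect_false(rs$negative_signal)
  # identical curves: zero everywhere
  all0 <- delta_auc_all(pre, pre, part)
  expect_true(all(all0$delta_auc == 0))
  # post brighter than pre: negative, flagged
  neg <- delta_auc(post, pre, part, "R1")
  expect_identical(neg$delta_auc, -2)
  expect_true(neg$negative_signal)
  expect_error(delta_auc(pre, area_curve(c(1, 2)), part, "R1"), "length")
})

test_that("rescaling slice count rescales regions proportionally", {
  for (n in c(32, 64, 128)) {
    lm <- landmarks(0, round(0.47 * n), round(0.70 * n), n - 1)
    part <- partition_regions(lm, n)
    frac_r4 <- length(region_slices(part, "R4")) / n
    expect_lt(abs(frac_r4 - 0.23), 2.5 / n + 0.01)
  }
})
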