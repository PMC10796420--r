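test_that("vulnerability index worked cases are exact", {
  expect_identical(vulnerability_index(30, 20, 20, 30)$index, 1)
  expect_identical(vulnerability_index(60, 20, 10, 10)$index, 4)
  expect_error(vulnerability_index(10, 0, 0, 0), "zero")
  expect_error(vulnerability_index(110, 0, 10, 10), "\\[0, 100\\]")
  expect_error(vulnerability_index(-1, 0, 10, 10), "\\[0, 100\\]")
})

test_that("vulnerability index is monotone in each argument", {
  set.seed(41)
  for (i in 1:50) {
    m <- runif(1, 1, 60); n <- runif(1, 0, 30)
    s <- runif(1, 1, 40); c0 <- runif(1, 1, 40)
    base <- vulnerability_index(m, n, s, c0)$index
    eps <- runif(1, 0.5, 5)
    expect_gt(vulnerability_index(min(m + eps, 100), n, s, c0)$index, base)
    expect_gt(vulnerability_index(m, min(n + eps, 100), s, c0)$index, base)
    expect_lt(vulnerability_index(m, n, min(s + eps, 100), c0)$index, base)
    expect_lt(vulnerability_index(m, n, s, min(c0 + eps, 100))$index, base)
  }
})

test_that("AHA typing matches the exhaustive precedence oracle", {
  flags <- expand.grid(foam_cells = c(FALSE, TRUE),
                       lipid_pools = c(FALSE, TRUE),
                       lipid_core = c(FALSE, TRUE),
                       necrotic_core = c(FALSE, TRUE),
                       surface_defect = c(FALSE, TRUE),
                       haemorrhage = c(FALSE, TRUE))
  got <- classify_aha(flags$foam_cells, flags$lipid_pools, flags$lipid_core,
                      flags$necrotic_core, flags$surface_defect,
                      flags$haemorrhage)
  # independent precedence-table oracle: highest present feature wins
  lvl <- c("I", "II", "III", "IV", "V", "VI")
  oracle <- apply(flags, 1, function(f) {
    idx <- c(1,
             if (f["foam_cells"]) 2, if (f["lipid_pools"]) 3,
             if (f["lipid_core"]) 4, if (f["necrotic_core"]) 5,
             if (f["surface_defect"] || f["haemorrhage"]) 6)
    lvl[max(idx)]
  })
  expect_identical(as.character(got), oracle)
  expect_s3_class(got, "ordered")

  # monotonicity: adding any single flag never lowers the type
  for (i in seq_len(nrow(flags))) for (j in seq_len(ncol(flags))) {
    f2 <- flags[i, ]; f2[[j]] <- TRUE
    t2 <- classify_aha(f2$foam_cells, f2$lipid_pools, f2$lipid_core,
                       f2$necrotic_core, f2$surface_defect, f2$haemorrhage)
    expect_gte(as.integer(t2), as.integer(got[i]))
  }
})

test_that("specific feature combinations map to the published types", {
  expect_identical(as.character(classify_aha(TRUE, FALSE, FALSE, FALSE,
                                             FALSE, FALSE)), "II")
  # complex plaque: surface defect dominates necrotic and lipid cores
  expect_identical(as.character(classify_aha(FALSE, FALSE, TRUE, TRUE,
                                             TRUE, FALSE)), "VI")
  # haemorrhage alone is also type VI
  expect_identical(as.character(classify_aha(FALSE, FALSE, FALSE, FALSE,
                                             FALSE, TRUE)), "VI")
  expect_identical(as.character(classify_aha(FALSE, FALSE, FALSE, FALSE,
                                             FALSE, FALSE)), "I")
})

test_that("biomarker aggregation means and keys follow the group-by oracle", {
  tab <- tibble::tibble(
    animal_id = c("a", "a", "a", "a", "b", "b"),
    region = c("R1", "R1", "R2", "R4", "R1", "R1"),
    pct_moma2 = c(10, 30, 5, 1, 7, 9),
    pct_sma = c(4, 6, 8, 2, 10, 20),
    mpio_fluorescence = c(1, 3, 5, 0, 2, 4)
  )
  agg <- aggregate_region_biomarkers(tab)
  expect_identical(nrow(agg), 4L)  # (a,R1), (a,R2), (a,R4), (b,R1)
  a_r1 <- agg[agg$animal_id == "a" & agg$region == "R1", ]
  expect_identical(a_r1$pct_moma2, 20)
  expect_identical(a_r1$pct_sma, 5)
  expect_identical(a_r1$mpio_fluorescence, 2)
  expect_identical(a_r1$n_sections, 2L)
  expect_identical(agg$excluded, agg$region == "R4")
  expect_error(aggregate_region_biomarkers(tab[0, ]), "empty")
})

test_that("AHA distributions reproduce stated compositions and sum to 100", {
  # 100 sections: 41 with surface defects (and necrotic cores), 59 with
  # necrotic cores only -> 41% type VI, 59% type V
  tab <- tibble::tibble(
    animal_id = "x", region = "R1",
    foam_cells = TRUE, lipid_pools = TRUE, lipid_core = TRUE,
    necrotic_core = TRUE,
    surface_defect = rep(c(TRUE, FALSE), c(41, 59)),
    haemorrhage = FALSE
  )
  d <- aha_distribution(tab)
  expect_identical(d$percent[d$aha_type == "VI"], 41)
  expect_identical(d$percent[d$aha_type == "V"], 59)

  # identical flags: 100% in one type
  tab2 <- tab; tab2$surface_defect <- TRUE
  d2 <- aha_distribution(tab2)
  expect_identical(d2$percent, 100)
  expect_identical(d2$aha_type, "VI")

  # three sections of types II / III / IV under the largest-remainder rule
  tab3 <- tibble::tibble(
    animal_id = "y", region = "R2",
    foam_cells = TRUE, lipid_pools = c(FALSE, TRUE, TRUE),
    lipid_core = c(FALSE, FALSE, TRUE), necrotic_core = FALSE,
    surface_defect = FALSE, haemorrhage = FALSE
  )
  d3 <- aha_distribution(tab3)
  expect_identical(sum(d3$percent), 100)
  expect_true(all(d3$percent %in% c(33.3, 33.4)))
})
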