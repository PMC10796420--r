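test_that("identical samples give t = 0, p = 1; strong effects give tiny p", {
  res <- compare_groups(rep(2, 5), rep(2, 5))
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)
  expect_false(res$significant)

  # closed-form check: n = 8 vs 8, means 10 vs 0, sd = 1
  set.seed(51)
  x <- rnorm(8, 10, 1); y <- rnorm(8, 0, 1)
  res2 <- compare_groups(x, y)
  sp <- sqrt(((7 * var(x)) + (7 * var(y))) / 14)
  t_oracle <- (mean(x) - mean(y)) / (sp * sqrt(1 / 8 + 1 / 8))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 14)
  expect_equal(res2$statistic, t_oracle)
  expect_equal(res2$p_value, p_oracle)
  expect_lt(res2$p_value, 1e-6)

  # constant samples with different means are maximally significant
  res3 <- compare_groups(rep(1, 4), rep(0, 4))
  expect_identical(res3$p_value, 0)
})

test_that("region comparisons cover all pairs among R1,R2,R3,R5 and drop R4", {
  set.seed(52)
  vals <- list(R1 = rnorm(8, 10), R2 = rnorm(8, 9), R3 = rnorm(8, 3),
               R4 = rnorm(8, 0), R5 = rnorm(8, 1))
  res <- compare_regions(vals)
  expect_identical(nrow(res), 6L)
  expect_false(any(grepl("R4", res$contrast)))
  expect_true(all(c("R1 vs R2", "R1 vs R3", "R1 vs R5", "R2 vs R3",
                    "R2 vs R5", "R3 vs R5") %in% res$contrast))
  expect_true(all(res$p_holm >= res$p_value))
  expect_error(compare_regions(list(R1 = rnorm(3), R2 = 1)), "fewer than 2")
  expect_error(compare_regions(list(R4 = rnorm(3))), "at least two")
})

test_that("Welch option changes the test under unequal variances", {
  set.seed(53)
  x <- rnorm(20, 0, 5); y <- rnorm(6, 0, 0.2)
  a <- compare_groups(x, y, var_equal = TRUE)
  b <- compare_groups(x, y, var_equal = FALSE)
  expect_false(isTRUE(all.equal(a$p_value, b$p_value)))
})

test_that("correlations recover exact linear relationships and the formula", {
  x <- c(1, 2, 4, 5, 7, 9)
  expect_equal(correlate_signal_biomarkers(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_signal_biomarkers(x, -x)$r, -1)

  y <- c(2.3, 1.1, 4.0, 3.7, 8.1, 7.7)
  res <- correlate_signal_biomarkers(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle)
  expect_identical(res$n, 6L)

  # Pearson r is invariant to affine rescaling of either variable
  expect_equal(correlate_signal_biomarkers(10 * x - 3, y)$r, res$r)
  expect_equal(correlate_signal_biomarkers(x, y / 7 + 100)$r, res$r)

  expect_error(correlate_signal_biomarkers(x, rep(1, 6)), "variance")
  expect_error(correlate_signal_biomarkers(x[1:2], y[1:2]), "at least 3")
  expect_error(correlate_signal_biomarkers(x, y[1:3]), "equal length")
  # Spearman depends only on ranks
  expect_equal(correlate_signal_biomarkers(x, exp(y),
                                           method = "spearman")$r,
               correlate_signal_biomarkers(x, y, method = "spearman")$r)
})

test_that("longitudinal report has the expected cardinality and determinism", {
  des <- cohort_design(n_animals = c(3, 3, 2, 2), weeks = c(10, 30))
  co <- generate_cohort(des, small_config(), seed = 33)
  sig <- quantify_cohort(co, search_radius = 0, threshold = 60)
  rep1 <- longitudinal_report(sig, histology = co$histology)
  # 4 arms x 2 weeks x 5 regions rows for the cuffed artery
  rcca <- rep1$summary[rep1$summary$side == "RCCA", ]
  expect_identical(nrow(rcca), 4L * 2L * 5L)
  # single-animal cells keep means and flag sd as NA
  one <- cohort_design(n_animals = c(1, 1, 1, 1), weeks = c(10, 30))
  co1 <- generate_cohort(one, small_config(), seed = 34)
  sig1 <- quantify_cohort(co1, search_radius = 0, threshold = 60)
  s1 <- longitudinal_report(sig1)$summary
  expect_true(all(is.na(s1$sd)))
  expect_identical(s1$mean[1], sig1$delta_auc[
    sig1$probe == s1$probe[1] & sig1$treatment == s1$treatment[1] &
      sig1$week == s1$week[1] & sig1$side == s1$side[1] &
      sig1$region == s1$region[1]])

  # rerun on regenerated inputs: byte-identical CSV output
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_report(rep1, d1)
  co_b <- generate_cohort(des, small_config(), seed = 33)
  sig_b <- quantify_cohort(co_b, search_radius = 0, threshold = 60)
  write_report(longitudinal_report(sig_b, histology = co_b$histology), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})
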