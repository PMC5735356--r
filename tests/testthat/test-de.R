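test_that("TPM normalization follows the count-over-total formula", {
  expect_equal(tpm(100, 1e6), 100)
  expect_equal(tpm(0, 123), 0)
  expect_equal(round(tpm(194, 11023426), 2), 17.60)
  expect_equal(tpm(c(1, 10), 2e6), c(0.5, 5))
  expect_error(tpm(5, 0), "positive")
  expect_error(tpm(-1, 10), "non-negative")
})

test_that("zero and low-expression rules modify and drop rows correctly", {
  m <- rbind(a = c(0, 5), b = c(0.5, 0.9), c = c(0.5, 1.2), d = c(0, 0))
  out <- apply_zero_and_low_rules(m)
  expect_equal(rownames(out), c("a", "c"))
  expect_equal(unname(out["a", ]), c(0.01, 5))
  expect_equal(unname(out["c", ]), c(0.5, 1.2))
  wide <- matrix(c(0.5, 0.9, 0.2, 0.7, 0.3), 1,
                 dimnames = list("x", NULL))
  expect_equal(nrow(apply_zero_and_low_rules(wide)), 0)
})

test_that("log2 fold-change reproduces published TPM pairs", {
  expect_equal(log2_fold_change(3.92, 17.64), -2.169925, tolerance = 1e-3)
  expect_equal(log2_fold_change(2.6, 17.64), -2.762267, tolerance = 1e-3)
  expect_equal(log2_fold_change(7.5, 7.5), 0)
  expect_error(log2_fold_change(0, 5), "zero rule")
})

test_that("exact-test pmf matches hand values and the factorial oracle", {
  expect_equal(ac_pmf(0, 0, 1), 0.5)
  expect_equal(ac_pmf(1, 0, 1), 0.25)
  for (ratio in c(0.5, 1, 2)) {
    grid <- expand.grid(x = 0:30, y = 0:30)
    got <- ac_pmf(grid$y, grid$x, ratio)
    want <- pmf_factorial(grid$y, grid$x, ratio)
    expect_lt(max(abs(got - want) / want), 1e-10)
  }
  for (x in c(0, 1, 5, 20)) for (ratio in c(0.5, 1, 2))
    expect_equal(sum(ac_pmf(0:10000, x, ratio)), 1, tolerance = 1e-9)
  expect_error(ac_pmf(-1, 0, 1), "non-negative")
  expect_error(ac_pmf(1, 1, 0), "positive")
})

test_that("two-tailed p-value behaves at the boundaries and symmetries", {
  # equal counts at equal totals sit in the centre of the distribution
  for (x in c(0, 3, 10, 50)) {
    p <- ac_pvalue(x, x, 1e6, 1e6)
    lower <- sum(ac_pmf(0:x, x, 1))
    upper <- 1 - lower + ac_pmf(x, x, 1)
    expect_equal(p, min(1, 2 * min(lower, upper)))
    expect_gte(p, 0.5)
  }
  expect_lt(ac_pvalue(100, 0, 1e6, 1e6), 1e-20)
  # the pmf is symmetric in the two counts at equal totals; the tail-based
  # p-value conditions on the control count, so only the pmf symmetry is exact
  expect_equal(ac_pmf(19, 7, 1), ac_pmf(7, 19, 1))
  # more extreme y at fixed x gives smaller p
  ps <- ac_pvalue(rep(20, 5), c(21, 30, 45, 70, 110), 1e6, 1e6)
  expect_true(all(diff(ps) < 0))
})

test_that("Bonferroni multiplies by the family size and caps at one", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(c(0.9, 0.9)), c(1, 1))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("de_table calls planted effects and respects the zero rule", {
  counts <- data.frame(mirna_id = c("m1", "m2", "m3", "m4"),
                       TW = c(500L, 40L, 200L, 0L),
                       h12 = c(60L, 45L, 0L, 3L))
  totals <- c(TW = 1e6, h12 = 1e6)
  de <- de_table(counts, "TW", "h12", totals)
  expect_equal(de$mirna_id, counts$mirna_id)
  m3 <- de[de$mirna_id == "m3", ]
  expect_equal(m3$tpm_treatment, 0.01)
  expect_equal(m3$log2fc, log2(0.01 / 200))
  # identical libraries: no significant calls
  same <- de_table(data.frame(mirna_id = c("a", "b"),
                              TW = c(100L, 7L), h12 = c(100L, 7L)),
                   "TW", "h12", totals)
  expect_false(any(same$significant))
  expect_true(all(same$fdr >= same$pvalue))
  # strong planted effect at high depth is called
  strong <- de_table(data.frame(mirna_id = "hit", TW = 400L, h12 = 3200L),
                     "TW", "h12", totals)
  expect_true(strong$significant)
  expect_equal(strong$log2fc, 3)
  expect_error(de_table(counts, "TW", "h12", c(TW = 0, h12 = 1)),
               "positive")
  expect_error(de_table(counts, "TW", "nope", totals), "count columns")
})

test_that("null simulations keep the type-I error near nominal", {
  sim <- simulate_mirna_counts(rep(100, 2000), 0, 1e6, 1e6, seed = 21)
  p <- ac_pvalue(sim$count_control, sim$count_treatment, 1e6, 1e6)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("top-N ranking keeps commonly expressed miRNAs in count order", {
  top <- study_top_counts()[, -2]  # drop the sequence column
  ranked <- top_n_abundant(top, "TW", 1)
  expect_equal(ranked$mirna_id, "pxy-mir-1-3p")
  expect_equal(ranked$TW, 371221)
  all10 <- top_n_abundant(top, "TW", 99)
  expect_equal(nrow(all10), 10)
  expect_true(all(diff(all10$TW) <= 0))
  withzero <- rbind(top, data.frame(mirna_id = "zz", TW = 999999, `12h` = 0,
                                    `18h` = 1, `24h` = 1, `36h` = 1,
                                    check.names = FALSE))
  expect_false("zz" %in% top_n_abundant(withzero, "TW", 99)$mirna_id)
  ties <- data.frame(mirna_id = c("b", "a"), TW = c(5L, 5L),
                     h12 = c(1L, 1L))
  expect_equal(top_n_abundant(ties, "TW", 2)$mirna_id, c("a", "b"))
})

test_that("tag counts aggregate to mature miRNAs including isomiRs", {
  mature <- c(m1 = "TACGCATGCATTACGCATGCAT", m2 = "GGATCCGGATCCGGATCCGG")
  tags <- data.frame(
    sequence = c(mature[["m1"]], substr(mature[["m1"]], 2, 22),
                 mature[["m2"]], "TTTTTGTGTGTGTGTTTTTT"),
    count = c(10L, 4L, 7L, 99L))
  mc <- mirna_counts(tags, mature)
  expect_equal(mc$count[mc$mirna_id == "m1"], 14L)
  expect_equal(mc$count[mc$mirna_id == "m2"], 7L)
})
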