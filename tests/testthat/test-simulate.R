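test_that("reference generation is seeded, constructive and byte-stable", {
  cfg <- sim_config(n_mirnas = 10, reads_per_library = 1000, seed = 1)
  refs <- generate_references(cfg)
  expect_length(refs$mature, 10)
  expect_true(all(nchar(refs$mature) >= 18 & nchar(refs$mature) <= 24))
  # every precursor contains its mature arm as an exact substring
  expect_true(all(mapply(grepl, refs$mature, refs$precursor, fixed = TRUE)))
  expect_true(all(vapply(names(refs$classes), function(cl)
    length(refs$classes[[cl]]) >= 1, logical(1))))
  expect_equal(sum(refs$abundance), 1)

  refs2 <- generate_references(cfg)
  d1 <- file.path(tempdir(), "refs1"); d2 <- file.path(tempdir(), "refs2")
  write_references(refs, d1); write_references(refs2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("precursor construction embeds a given mature sequence", {
  mature <- "TGGAATGTAAAGAAGTATGGAG"
  pre <- smrnade:::with_seed(7, smrnade:::make_precursor(mature))
  expect_true(grepl(mature, pre, fixed = TRUE))
  expect_gte(nchar(pre), 2 * nchar(mature))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(class_fractions = c(miRNA = 1)), "class_fractions")
  expect_error(sim_config(adapter_3p = "ACGTX"), "alphabet")
  expect_error(sim_config(contamination_fractions = c(polyA = 1)), "\\[0, 1\\)")
  cfg <- sim_config(n_mirnas = 5, reads_per_library = 500,
                    planted_effects = data.frame(
                      mirna_id = "no-such-mir", library_id = "12h",
                      log2_fold_change = 2))
  refs <- generate_references(cfg)
  expect_error(generate_library(cfg, refs, "12h"), "no-such-mir")
  expect_error(generate_library(cfg, refs, "nope"), "unknown library")
})

test_that("library generation is deterministic and adapters behave", {
  cfg <- sim_config(n_mirnas = 15, reads_per_library = 1500, seed = 11,
                    contamination_fractions = c(low_quality = 0))
  refs <- generate_references(cfg)
  lib <- generate_library(cfg, refs, "TW")
  lib2 <- generate_library(cfg, refs, "TW")
  expect_identical(as.character(lib$reads), as.character(lib2$reads))
  expect_identical(lib$truth, lib2$truth)
  # zero contamination: every read carries the 3' adapter
  expect_true(all(grepl(cfg$adapter_3p, as.character(lib$reads),
                        fixed = TRUE)))
})

test_that("per-class read fractions converge to the configured mixture", {
  cfg <- sim_config(n_mirnas = 30, reads_per_library = 30000, seed = 2,
                    contamination_fractions = c(low_quality = 0))
  refs <- generate_references(cfg)
  lib <- generate_library(cfg, refs, "TW")
  tab <- table(lib$truth$category)
  n <- sum(tab)
  for (cl in names(cfg$class_fractions)) {
    p <- cfg$class_fractions[[cl]]
    sigma <- sqrt(p * (1 - p) / n)
    expect_lt(abs(tab[[cl]] / n - p), 3 * sigma + 1e-12,
              label = paste("class fraction for", cl))
  }
})

test_that("insert length histogram peaks at the configured lengths", {
  for (seed in c(1, 9)) {
    cfg <- sim_config(n_mirnas = 40, reads_per_library = 20000, seed = seed)
    refs <- generate_references(cfg)
    lib <- generate_library(cfg, refs, "TW")
    pp <- filter_and_trim(lib$reads, cfg$adapter_3p, cfg$adapter_5p)
    ld <- length_distribution(pp$tags)
    top2 <- ld$length[order(-ld$count)][1:2]
    expect_setequal(top2, cfg$length_peaks)
  }
})

test_that("planted fold-changes scale expected counts and TPM exactly", {
  pe <- data.frame(mirna_id = c("sim-mir-003", "sim-mir-005"),
                   library_id = c("12h", "12h"),
                   log2_fold_change = c(-2.169925, 1.5))
  cfg <- sim_config(n_mirnas = 8, reads_per_library = 2000, seed = 4,
                    planted_effects = pe)
  refs <- generate_references(cfg)
  ctl <- generate_library(cfg, refs, "TW")$expected_mirna_counts
  trt <- generate_library(cfg, refs, "12h")$expected_mirna_counts
  ratio <- trt$expected_count / ctl$expected_count
  expect_equal(ratio[ctl$mirna_id == "sim-mir-003"], 2^-2.169925)
  expect_equal(ratio[ctl$mirna_id == "sim-mir-005"], 2^1.5)
  expect_equal(ratio[!ctl$mirna_id %in% pe$mirna_id],
               rep(1, 6))
  # at equal clean totals the expected TPM pair reproduces the published
  # control/treatment pair shape: 17.64 TPM falling to 3.92
  expect_equal(round(17.64 * 2^-2.169925, 2), 3.92)
})

test_that("count-level simulator honours depth and fold-change", {
  sim <- simulate_mirna_counts(base_tpm = rep(100, 2000),
                               log2_fold_change = c(1, rep(0, 1999)),
                               depth_control = 1e6, depth_treatment = 2e6,
                               seed = 8)
  # treatment depth doubles expected counts; the planted miRNA doubles again
  expect_equal(mean(sim$count_control), 100, tolerance = 0.05)
  expect_equal(mean(sim$count_treatment[-1]), 200, tolerance = 0.05)
  expect_gt(sim$count_treatment[1], 250)
  sim2 <- simulate_mirna_counts(rep(100, 2000), c(1, rep(0, 1999)),
                                1e6, 2e6, seed = 8)
  expect_identical(sim, sim2)
})
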