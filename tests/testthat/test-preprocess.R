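test_that("each read lands in exactly one category by the fixed rule order", {
  ad3 <- TEST_ADAPTER3; ad5 <- TEST_ADAPTER5
  insert22 <- "CATGCTAGCTAGCTAGCTAGCT"
  cases <- list(
    low_quality_phred = list(seq = paste0(insert22, ad3),
                             qual = strrep("+", 22 + nchar(ad3)),
                             cat = "low_quality"),
    low_quality_n = list(seq = paste0("CATGCTAGCTAGCTAGCTAGCN", ad3),
                         cat = "low_quality"),
    no_adapter = list(seq = "CATGCTAGCTAGCTAGCTAGCTCATGCTAGCTAGCTAG",
                      cat = "three_prime_adapter_null"),
    empty_insert = list(seq = paste0(ad3, "GATTACA"), cat = "insert_null"),
    five_prime = list(seq = paste0(substr(ad5, 5, 14), insert22, ad3),
                      cat = "five_prime_contaminant"),
    sixteen_nt = list(seq = paste0("CATGCTAGCTAGCTAG", ad3),
                      cat = "shorter_than_18"),
    polya = list(seq = paste0("AAAAAAAAAAAAAAAAAACGA", ad3), cat = "polyA"),
    clean = list(seq = paste0(insert22, ad3), cat = "clean"),
    adapter_at_end = list(seq = paste0(insert22, substr(ad3, 1, 7)),
                          cat = "clean"))
  seqs <- vapply(cases, `[[`, character(1), "seq")
  quals <- vapply(cases, function(cs)
    if (is.null(cs$qual)) strrep("I", nchar(cs$seq)) else cs$qual,
    character(1))
  res <- filter_and_trim(make_reads(seqs, quals), ad3, ad5)
  expect_equal(as.character(res$category),
               unname(vapply(cases, `[[`, character(1), "cat")))
  # category counts partition the high-quality total
  acc <- res$accounting
  hq <- acc$count[acc$category == "high_quality_reads"]
  expect_equal(sum(acc$count[!acc$category %in%
                               c("high_quality_reads")]), hq)
  expect_equal(hq, length(seqs) - 2)  # two low-quality reads removed first
  # clean inserts are adapter-trimmed
  expect_equal(unname(res$inserts), c(insert22, insert22))
})

test_that("filtering pre-trimmed clean inserts removes nothing", {
  inserts <- c("CATGCTAGCTAGCTAGCTAGCT", "GGTACCGGTACCGGTACCGGT",
               "TTGACTGACTGACTGACTGACTGACTGA")
  res <- filter_and_trim(make_reads(inserts), adapter_3p = NULL)
  expect_true(all(res$category == "clean"))
  expect_setequal(unname(res$inserts), inserts)
})

test_that("empty input yields empty accounting, not an error", {
  res <- filter_and_trim(make_reads(character(0)), TEST_ADAPTER3)
  expect_equal(nrow(res$tags), 0)
  expect_true(all(res$accounting$count == 0))
})

test_that("accounting percentages reproduce the printed convention", {
  acc <- filter_accounting(high_quality_total = 11861547,
                           three_prime_adapter_null = 27731,
                           insert_null = 8951,
                           five_prime_contaminant = 205353,
                           shorter_than_18 = 595179, polyA = 907)
  get <- function(cat, col) acc[[col]][acc$category == cat]
  expect_equal(get("clean", "count"), 11023426)
  expect_equal(get("clean", "percent"), 92.93)
  expect_equal(get("shorter_than_18", "percent"), 5.02)
  expect_equal(get("insert_null", "percent"), 0.08)
  expect_error(filter_accounting(10, 20, 0, 0, 0, 0), "exceed")
  expect_error(filter_accounting(10, -1, 0, 0, 0, 0), "non-negative")
})

test_that("tag collapsing conserves mass and orders deterministically", {
  expect_equal(collapse_tags(c("S1", "S1", "S2")),
               data.frame(sequence = c("S1", "S2"), count = c(2L, 1L)))
  distinct <- c("TTA", "AAC", "CCG")
  expect_true(all(collapse_tags(distinct)$count == 1))
  # ties break lexicographically
  expect_equal(collapse_tags(c("B", "A", "C"))$sequence, c("A", "B", "C"))
  cfg <- sim_config(n_mirnas = 10, reads_per_library = 3000, seed = 6)
  refs <- generate_references(cfg)
  lib <- generate_library(cfg, refs, "18h")
  res <- filter_and_trim(lib$reads, cfg$adapter_3p, cfg$adapter_5p)
  clean_count <- res$accounting$count[res$accounting$category == "clean"]
  expect_equal(sum(res$tags$count), clean_count)
  expect_equal(length(res$inserts), clean_count)
})

test_that("length distribution is mass-weighted and sums to 100", {
  one <- data.frame(sequence = strrep("A", 22), count = 10L)
  expect_equal(length_distribution(one),
               data.frame(length = 22L, count = 10L, percent = 100))
  two <- data.frame(sequence = c(strrep("A", 22), strrep("C", 28)),
                    count = c(5L, 5L))
  ld <- length_distribution(two)
  expect_equal(ld$percent, c(50, 50))
  many <- data.frame(sequence = c(strrep("G", 19), strrep("C", 19),
                                  strrep("T", 25)),
                     count = c(3L, 9L, 1L))
  ld <- length_distribution(many)
  expect_equal(sum(ld$percent), 100, tolerance = 1e-6)
  expect_equal(ld$count[ld$length == 19], 12L)
  expect_error(length_distribution(collapse_tags(character(0))),
               "no clean tags")
})
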