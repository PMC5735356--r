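# Read filtering, adapter trimming, tag collapsing and library accounting.
#
# High-quality reads are assigned to exactly one category, in the fixed
# order used by library accounting tables for this design:
#   low-quality (removed before accounting; the remainder is the
#   high-quality total) -> 3' adapter-null -> insert-null ->
#   5' adapter-contaminant -> shorter than 18 nt -> polyA -> clean.
# Category definitions the sequencing reports leave implicit are fixed here:
# low-quality = mean Phred < 20 or any N; insert-null = 3' adapter at
# position 1 (empty insert); 5' contaminant = first 8 nt of the insert occur
# within the 5' adapter; polyA = >= 80% A after trimming.

#' Preprocessing parameters
#'
#' @param min_insert_len minimum insert length kept as clean (nt).
#' @param min_adapter_overlap minimum 3' adapter prefix match (nt).
#' @param low_quality_mean_phred reads with mean Phred below this (or any N
#'   base) are removed as low-quality.
#' @param five_prime_min_match first-k-nt match length against the 5'
#'   adapter that flags a 5' contaminant.
#' @param polya_fraction minimum A fraction that flags a polyA insert.
#' @return list of parameters.
#' @export
preprocess_params <- function(min_insert_len = 18L,
                              min_adapter_overlap = 6L,
                              low_quality_mean_phred = 20,
                              five_prime_min_match = 8L,
                              polya_fraction = 0.8) {
  list(min_insert_len = as.integer(min_insert_len),
       min_adapter_overlap = as.integer(min_adapter_overlap),
       low_quality_mean_phred = low_quality_mean_phred,
       five_prime_min_match = as.integer(five_prime_min_match),
       polya_fraction = polya_fraction)
}

#' Read a FASTQ file (Phred+33, optionally gzipped)
#'
#' @param path FASTQ path.
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # Biostrings notes that it drops (empty) metadata columns on read
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Leftmost position in `read` where a prefix of the 3' adapter of length
# >= min_overlap matches exactly (the match may run off the read end).
# Returns NA if no such position, or the 1-based insert end + 1.
find_adapter <- function(read, adapter, min_overlap) {
  n <- nchar(read)
  seed <- substr(adapter, 1, min_overlap)
  # lookahead so that overlapping seed occurrences are all candidates
  hits <- gregexpr(paste0("(?=", seed, ")"), read, perl = TRUE)[[1]]
  if (hits[1] != -1) {
    for (pos in hits) {
      k <- min(nchar(adapter), n - pos + 1)
      if (substr(read, pos, pos + k - 1) == substr(adapter, 1, k))
        return(pos)
    }
  }
  # adapter truncated at the read end with overlap in [min_overlap, seed)
  # is already covered by the seed search; nothing else to try
  NA_integer_
}

#' Filter and trim a small RNA library
#'
#' Assigns every read to exactly one removal category or to the clean set,
#' trims the 3' adapter from clean reads, collapses clean inserts to unique
#' tags and returns the per-category accounting.
#'
#' Percentages in the accounting are relative to the high-quality total
#' (reads surviving the low-quality filter), half-up rounded to 2 decimals,
#' matching the presentation convention of sequencing reports.
#'
#' If `adapter_3p` is `NULL` the input is treated as already trimmed: the
#' adapter-dependent categories are skipped and each read is its own insert.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (see
#'   [read_fastq()]).
#' @param adapter_3p 3' adapter sequence, or `NULL` for pre-trimmed input.
#' @param adapter_5p 5' adapter sequence, or `NULL` to skip that check.
#' @param params see [preprocess_params()].
#' @return list with `category` (per-read factor), `inserts` (named
#'   character vector of clean inserts), `tags` (collapsed tag data frame,
#'   see [collapse_tags()]) and `accounting` (see [filter_accounting()]).
#' @export
filter_and_trim <- function(reads, adapter_3p, adapter_5p = NULL,
                            params = preprocess_params()) {
  if (length(reads) == 0) {
    return(list(category = factor(character(0),
                                  levels = c(FILTER_CATEGORIES, "clean")),
                inserts = character(0),
                tags = data.frame(sequence = character(0),
                                  count = integer(0)),
                accounting = filter_accounting(0, 0, 0, 0, 0, 0)))
  }
  if (!is.null(adapter_3p)) assert_dna(adapter_3p, "adapter_3p")
  if (!is.null(adapter_5p)) assert_dna(adapter_5p, "adapter_5p")
  seqs <- as.character(reads)
  quals <- as.character(Biostrings::quality(reads))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(seqs))

  mean_phred <- vapply(quals, function(q) mean(utf8ToInt(q) - 33L),
                       numeric(1), USE.NAMES = FALSE)
  has_n <- grepl("N", seqs, fixed = TRUE)
  low_q <- mean_phred < params$low_quality_mean_phred | has_n

  category <- rep(NA_character_, length(seqs))
  category[low_q] <- "low_quality"
  insert <- rep(NA_character_, length(seqs))

  hq <- which(!low_q)
  if (is.null(adapter_3p)) {
    insert[hq] <- seqs[hq]
    adapter_pos <- rep(NA_integer_, length(seqs))
  } else {
    adapter_pos <- rep(NA_integer_, length(seqs))
    adapter_pos[hq] <- vapply(seqs[hq], find_adapter, integer(1),
                              adapter = adapter_3p,
                              min_overlap = params$min_adapter_overlap,
                              USE.NAMES = FALSE)
    no_ad <- hq[is.na(adapter_pos[hq])]
    category[no_ad] <- "three_prime_adapter_null"
    null_ins <- hq[!is.na(adapter_pos[hq]) & adapter_pos[hq] == 1]
    category[null_ins] <- "insert_null"
    rest <- hq[is.na(category[hq])]
    insert[rest] <- substr(seqs[rest], 1, adapter_pos[rest] - 1)
  }
  rest <- which(!low_q & is.na(category))
  if (!is.null(adapter_5p)) {
    k <- params$five_prime_min_match
    head_k <- substr(insert[rest], 1, k)
    contam <- nchar(insert[rest]) >= k &
      vapply(head_k, grepl, logical(1), x = adapter_5p, fixed = TRUE,
             USE.NAMES = FALSE)
    category[rest[contam]] <- "five_prime_contaminant"
    rest <- rest[!contam]
  }
  short <- nchar(insert[rest]) < params$min_insert_len
  category[rest[short]] <- "shorter_than_18"
  rest <- rest[!short]
  a_frac <- vapply(insert[rest], function(s)
    lengths(regmatches(s, gregexpr("A", s, fixed = TRUE))) / nchar(s),
    numeric(1), USE.NAMES = FALSE)
  polya <- a_frac >= params$polya_fraction
  category[rest[polya]] <- "polyA"
  category[rest[!polya]] <- "clean"

  clean_idx <- which(category == "clean")
  inserts <- setNames(insert[clean_idx], ids[clean_idx])
  counts <- table(factor(category, levels = c(FILTER_CATEGORIES, "clean")))
  acc <- filter_accounting(
    high_quality_total = sum(counts) - counts[["low_quality"]],
    three_prime_adapter_null = counts[["three_prime_adapter_null"]],
    insert_null = counts[["insert_null"]],
    five_prime_contaminant = counts[["five_prime_contaminant"]],
    shorter_than_18 = counts[["shorter_than_18"]],
    polyA = counts[["polyA"]],
    low_quality = counts[["low_quality"]])
  list(category = factor(category, levels = c(FILTER_CATEGORIES, "clean")),
       inserts = inserts,
       tags = collapse_tags(inserts),
       accounting = acc)
}

#' Per-category library accounting
#'
#' Builds the removal-category accounting table from category counts: one
#' row per category plus the clean remainder, with percentages relative to
#' the high-quality total (half-up, 2 decimals). `clean` is derived as
#' `high_quality_total - sum(removed categories)`, so the categories
#' partition the total exactly.
#'
#' @param high_quality_total reads surviving the low-quality filter.
#' @param three_prime_adapter_null,insert_null,five_prime_contaminant
#'   category counts.
#' @param shorter_than_18,polyA category counts.
#' @param low_quality reads removed before the high-quality total (not part
#'   of the percentage denominator; kept for completeness).
#' @return data frame with columns `category`, `count`, `percent`.
#' @export
filter_accounting <- function(high_quality_total, three_prime_adapter_null,
                              insert_null, five_prime_contaminant,
                              shorter_than_18, polyA, low_quality = 0) {
  counts <- c(high_quality_total, three_prime_adapter_null, insert_null,
              five_prime_contaminant, shorter_than_18, polyA)
  if (any(counts < 0)) stop("counts must be non-negative")
  removed <- three_prime_adapter_null + insert_null +
    five_prime_contaminant + shorter_than_18 + polyA
  if (removed > high_quality_total)
    stop("removed categories exceed the high-quality total")
  clean <- high_quality_total - removed
  df <- data.frame(
    category = c("high_quality_reads", "three_prime_adapter_null",
                 "insert_null", "five_prime_contaminant",
                 "shorter_than_18", "polyA", "clean"),
    count = c(high_quality_total, three_prime_adapter_null, insert_null,
              five_prime_contaminant, shorter_than_18, polyA, clean),
    stringsAsFactors = FALSE)
  df$percent <- if (high_quality_total > 0)
    percent_of(df$count, high_quality_total) else 0
  attr(df, "low_quality") <- low_quality
  df
}

#' Collapse clean inserts into unique tags with counts
#'
#' @param inserts character vector of trimmed clean inserts.
#' @return data frame (`sequence`, `count`) sorted by descending count with
#'   lexicographic tie-break; total count equals `length(inserts)`.
#' @export
collapse_tags <- function(inserts) {
  if (length(inserts) == 0)
    return(data.frame(sequence = character(0), count = integer(0)))
  tab <- table(inserts)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Length distribution of clean tags
#'
#' Frequencies are weighted by tag count (read mass), not by unique tags.
#'
#' @param tags data frame from [collapse_tags()].
#' @return data frame (`length`, `count`, `percent`); percentages sum
#'   to 100.
#' @export
length_distribution <- function(tags) {
  if (nrow(tags) == 0) stop("no clean tags")
  len <- nchar(tags$sequence)
  agg <- tapply(tags$count, len, sum)
  df <- data.frame(length = as.integer(names(agg)),
                   count = as.integer(agg))
  df <- df[order(df$length), , drop = FALSE]
  df$percent <- 100 * df$count / sum(df$count)
  rownames(df) <- NULL
  df
}

#' Write preprocessing outputs as TSV
#'
#' @param result from [filter_and_trim()].
#' @param dir output directory.
#' @param prefix file-name prefix (e.g. the library id).
#' @return invisibly, the written paths.
#' @export
write_preprocess <- function(result, dir, prefix = "library") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tags = file.path(dir, paste0(prefix, "_tags.tsv")),
    accounting = file.path(dir, paste0(prefix, "_accounting.tsv")),
    lengths = file.path(dir, paste0(prefix, "_length_distribution.tsv")))
  write_tsv(result$tags, paths[["tags"]])
  write_tsv(result$accounting, paths[["accounting"]])
  if (nrow(result$tags) > 0)
    write_tsv(length_distribution(result$tags), paths[["lengths"]])
  invisible(paths)
}
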