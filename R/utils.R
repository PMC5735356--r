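# Internal helpers shared across modules.

#' @importFrom stats rpois rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over the `A/C/G/T/N` alphabet (U is treated
#' as T on input).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUNacgtun", "TGCAANtgcaan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# Half-up rounding (the convention used for printed percentages).
# The 1e-9 guard absorbs binary-representation error just below .xx5.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count relative to a total, half-up rounded to 2 decimals
#'
#' The presentation convention used throughout the accounting and mapping
#' summaries: `100 * count / total` rounded half-up to two decimals.
#'
#' @param count numeric count(s).
#' @param total positive total.
#' @return numeric percentage(s).
#' @export
percent_of <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0))
  round_half_up(100 * count / total, 2)
}

# Random DNA string(s); A-fraction capped so synthetic sequences are never
# mistaken for polyA contaminants or for each other's classes.
random_dna <- function(n, len, max_a_frac = 0.6) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    repeat {
      s <- sample(DNA_BASES, l, replace = TRUE)
      if (mean(s == "A") < max_a_frac) return(paste(s, collapse = ""))
    }
  }, character(1))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad))
    stop(what, " contains characters outside the A/C/G/T/N alphabet: ",
         x[which(bad)[1]], call. = FALSE)
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
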