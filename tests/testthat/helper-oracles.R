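# Independent oracles used to check the analytic implementations.

# Direct factorial evaluation of the exact-test pmf (usable for x+y small
# enough that factorials stay finite).
pmf_factorial <- function(y, x, ratio) {
  ratio^y * factorial(x + y) / (factorial(x) * factorial(y)) /
    (1 + ratio)^(x + y + 1)
}

# Exhaustive enumeration of all nested secondary structures on bases[i..j]
# with a minimum hairpin loop of `min_loop`; returns a list of two-column
# pair matrices. Independent of the dynamic program in fold_energy().
enum_structures <- function(bases, i, j, min_loop = 3L) {
  if (j - i < min_loop + 1L) return(list(matrix(numeric(0), 0, 2)))
  out <- enum_structures(bases, i + 1L, j, min_loop)     # i unpaired
  pairable <- c(GC = TRUE, CG = TRUE, AU = TRUE, UA = TRUE,
                GU = TRUE, UG = TRUE)
  for (k in (i + min_loop + 1L):j) {
    if (!isTRUE(pairable[paste0(bases[i], bases[k])])) next
    inner <- enum_structures(bases, i + 1L, k - 1L, min_loop)
    rest <- if (k < j) enum_structures(bases, k + 1L, j, min_loop)
            else list(matrix(numeric(0), 0, 2))
    for (a in inner) for (b in rest)
      out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
  }
  out
}

# Brute-force minimum energy by scoring every enumerated structure.
fold_energy_bruteforce <- function(sequence, model = rna_energy_model()) {
  bases <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  structs <- enum_structures(bases, 1L, length(bases), model$min_loop)
  min(vapply(structs, function(p) score_structure(sequence, p, model),
             numeric(1)))
}

# Overlapping dinucleotide counts as a named vector.
dinuc_counts <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < 2) return(table(character(0)))
  table(substring(s, 1:(n - 1), 2:n))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Assemble a QualityScaledDNAStringSet from plain strings (default Q40).
make_reads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
}

# A well-paired hairpin: GC-rich stem + tetraloop + perfect complement.
make_hairpin <- function(stem_len, seed = 1) {
  smrnade:::with_seed(seed, {
    stem <- paste(sample(c("G", "C", "A", "U"), stem_len, replace = TRUE,
                         prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    paste0(stem, "GAAA",
           chartr("ACGU", "UGCA",
                  paste(rev(strsplit(stem, "")[[1]]), collapse = "")))
  })
}

TEST_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
TEST_ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
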