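# Exact-match genome mapping and hierarchical tag annotation.
#
# Tags are classified by a fixed priority rule: structural RNA classes
# (rRNA, scRNA, snoRNA, snRNA, tRNA) > known miRNA > repeat > exon >
# intron; tags matching nothing are unannotated. A tag is assigned to the
# highest-priority class with a match, so per-class masses partition the
# clean mass.

RRNA_LIKE <- c("rRNA", "scRNA", "snoRNA", "snRNA", "tRNA")
CLASS_PRIORITY <- c("rRNA_like", "known_miRNA", "repeat", "exon", "intron",
                    "unannotated")

#' Map tags to a genome by exact substring match
#'
#' The mapping contract is exact substring match on either strand; aligner
#' heuristics (mismatches, seeds, multi-mapping policy) are out of scope.
#'
#' @param tags tag data frame (`sequence`, `count`).
#' @param genome genome as a single string, a named character vector of
#'   contigs, or a FASTA path.
#' @return list with `mapped` (per-tag logical), `mapped_mass`,
#'   `total_mass` and `percent` (mapped mass / clean mass, 2 decimals).
#' @export
map_exact <- function(tags, genome) {
  genome <- load_sequences(genome, "genome")
  if (sum(nchar(genome)) == 0) stop("genome is empty")
  hay <- paste(genome, collapse = "NN")   # tags cannot span contigs
  mapped <- vapply(tags$sequence, function(s)
    grepl(s, hay, fixed = TRUE) || grepl(revcomp(s), hay, fixed = TRUE),
    logical(1), USE.NAMES = FALSE)
  mm <- sum(tags$count[mapped])
  tm <- sum(tags$count)
  list(mapped = mapped, mapped_mass = mm, total_mass = tm,
       percent = percent_of(mm, tm))
}

# Accept a character vector, Biostrings set, or FASTA path.
load_sequences <- function(x, what) {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet"))
    return(setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x))
    return(setNames(as.character(Biostrings::readDNAStringSet(x)), NULL))
  if (is.character(x)) return(x)
  stop("cannot interpret ", what)
}

# Does `tag` hit a mature miRNA, tolerating small isomiR length offsets?
# Match = tag is a substring of the mature or vice versa, with a length
# difference of at most `offset_tolerance` nt.
match_mature <- function(tags, mature, offset_tolerance = 2L) {
  m_lens <- nchar(mature)
  vapply(tags, function(s) {
    l <- nchar(s)
    ok <- abs(m_lens - l) <= offset_tolerance
    any(vapply(which(ok), function(i) {
      if (l <= m_lens[i]) grepl(s, mature[i], fixed = TRUE)
      else grepl(mature[i], s, fixed = TRUE)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Classify tags by the annotation priority rule
#'
#' @param tags tag data frame (`sequence`, `count`).
#' @param reference_sets named list of reference sequence sets; recognised
#'   names are the structural classes (`rRNA`, `scRNA`, `snoRNA`, `snRNA`,
#'   `tRNA`), `repeat`, `exon` and `intron`. Each set may be a character
#'   vector, a Biostrings set or a FASTA path. A tag matches a class when
#'   it is an exact substring of any sequence in the set.
#' @param mature named character vector of mature miRNA sequences (the
#'   `known_miRNA` class); matching tolerates isomiR length offsets of up
#'   to `offset_tolerance` nt.
#' @param offset_tolerance see above (default 2).
#' @return factor of classes (`rRNA_like`, `known_miRNA`, `repeat`,
#'   `exon`, `intron`, `unannotated`), one per tag.
#' @export
classify_tags <- function(tags, reference_sets, mature,
                          offset_tolerance = 2L) {
  sets <- lapply(reference_sets, load_sequences, what = "reference set")
  groups <- list(
    rRNA_like = unlist(sets[names(sets) %in% RRNA_LIKE], use.names = FALSE),
    `repeat` = sets[["repeat"]],
    exon = sets[["exon"]],
    intron = sets[["intron"]])
  hay <- lapply(groups, function(g)
    if (is.null(g) || length(g) == 0) NULL else paste(g, collapse = "NN"))
  mature <- rna_to_dna(load_sequences(mature, "mature"))
  cls <- rep("unannotated", nrow(tags))
  unset <- rep(TRUE, nrow(tags))
  assign_class <- function(hits, label) {
    cls[unset & hits] <<- label
    unset <<- unset & !hits
  }
  if (!is.null(hay$rRNA_like))
    assign_class(vapply(tags$sequence, grepl, logical(1), x = hay$rRNA_like,
                        fixed = TRUE, USE.NAMES = FALSE), "rRNA_like")
  assign_class(match_mature(tags$sequence, mature, offset_tolerance),
               "known_miRNA")
  for (label in c("repeat", "exon", "intron")) {
    if (is.null(hay[[label]])) next
    assign_class(vapply(tags$sequence, grepl, logical(1), x = hay[[label]],
                        fixed = TRUE, USE.NAMES = FALSE), label)
  }
  factor(cls, levels = CLASS_PRIORITY)
}

#' Per-class composition of a tag set
#'
#' @param tags tag data frame (`sequence`, `count`).
#' @param classes factor from [classify_tags()].
#' @return data frame (`class`, `mass`, `percent`); masses sum to the
#'   total clean mass.
#' @export
class_composition <- function(tags, classes) {
  mass <- tapply(tags$count, classes, sum, default = 0)
  data.frame(class = names(mass), mass = as.numeric(mass),
             percent = percent_of(as.numeric(mass), sum(tags$count)),
             stringsAsFactors = FALSE)
}

#' Shared sequence mass between two libraries
#'
#' For each library, the fraction of its read mass carried by tags whose
#' sequence also occurs in the other library. The headline `percent` is the
#' combined convention: (shared mass in A + shared mass in B) / (total A +
#' total B), in percent. The one-sided fractions are reported alongside.
#'
#' @param tags_a,tags_b tag data frames (`sequence`, `count`).
#' @return list with `percent` (combined), `percent_a`, `percent_b`.
#' @export
pairwise_common <- function(tags_a, tags_b) {
  if (nrow(tags_a) == 0 || nrow(tags_b) == 0)
    stop("both tag sets must be non-empty")
  shared <- intersect(tags_a$sequence, tags_b$sequence)
  ma <- sum(tags_a$count[tags_a$sequence %in% shared])
  mb <- sum(tags_b$count[tags_b$sequence %in% shared])
  ta <- sum(tags_a$count); tb <- sum(tags_b$count)
  list(percent = percent_of(ma + mb, ta + tb),
       percent_a = percent_of(ma, ta),
       percent_b = percent_of(mb, tb))
}
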