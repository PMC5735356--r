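# Synthetic small RNA study generator.
#
# Emulates the structure of an insect small RNA sequencing experiment: one
# control library plus treatment libraries at several time points, a bimodal
# insert-length distribution (miRNA peak and piRNA-sized peak), a mixture of
# annotation classes, the six read-removal categories used in library
# accounting, and planted differential expression with known log2
# fold-changes. Everything is seeded and reproducible.

MIRNA_LEN_PROBS <- c(`18` = 0.02, `19` = 0.04, `20` = 0.08, `21` = 0.12,
                     `22` = 0.55, `23` = 0.14, `24` = 0.05)
PIRNA_LEN_PROBS <- c(`24` = 0.04, `25` = 0.07, `26` = 0.10, `27` = 0.12,
                     `28` = 0.45, `29` = 0.13, `30` = 0.09)

FILTER_CATEGORIES <- c("low_quality", "three_prime_adapter_null",
                       "insert_null", "five_prime_contaminant",
                       "shorter_than_18", "polyA")
ANNOTATION_CLASSES <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                        "repeat", "exon", "intron", "unannotated")

#' Configuration for the synthetic small RNA study
#'
#' Defines the study conditions for the seeded generator: library layout,
#' sequencing depth, annotation-class mixture, contamination fractions for
#' the read-removal categories, adapter sequences, insert-length peaks and
#' planted differential expression.
#'
#' Defaults emulate a five-library insect infection time course (one
#' Tween-treated control plus 12/18/24/36 h treatments) at desk scale:
#' 20,000 reads per library, 60 miRNAs with log-normal relative abundances,
#' contamination fractions close to those observed in real libraries of this
#' design, and insert lengths peaking at 22 nt (miRNA) and 28 nt
#' (piRNA-sized).
#'
#' @param n_libraries number of libraries (first is the control).
#' @param library_ids character ids, length `n_libraries`.
#' @param reads_per_library expected total reads per library (> 0).
#' @param n_mirnas number of mature miRNAs in the synthetic reference.
#' @param class_fractions named proportions over the annotation classes
#'   (miRNA, rRNA, tRNA, snRNA, snoRNA, repeat, exon, intron, unannotated);
#'   must sum to 1.
#' @param contamination_fractions named proportions in `[0, 1)` for the
#'   removal categories (low_quality, three_prime_adapter_null, insert_null,
#'   five_prime_contaminant, shorter_than_18, polyA).
#' @param planted_effects data frame with columns `mirna_id`, `library_id`,
#'   `log2_fold_change`; expected counts of that miRNA in that library are
#'   scaled by `2^log2_fold_change` relative to the control.
#' @param length_peaks two integers, the modal insert lengths (miRNA peak,
#'   piRNA-sized peak).
#' @param adapter_3p,adapter_5p adapter sequences (A/C/G/T).
#' @param seed integer RNG seed; identical configs regenerate byte-identical
#'   output.
#' @return an object of class `smrna_sim_config`.
#' @export
sim_config <- function(n_libraries = 5,
                       library_ids = c("TW", "12h", "18h", "24h", "36h"),
                       reads_per_library = 20000,
                       n_mirnas = 60,
                       class_fractions = c(miRNA = 0.30, rRNA = 0.08,
                                           tRNA = 0.05, snRNA = 0.02,
                                           snoRNA = 0.02, repeat. = 0.08,
                                           exon = 0.10, intron = 0.10,
                                           unannotated = 0.25),
                       contamination_fractions = c(low_quality = 0.010,
                                                   three_prime_adapter_null = 0.003,
                                                   insert_null = 0.001,
                                                   five_prime_contaminant = 0.017,
                                                   shorter_than_18 = 0.050,
                                                   polyA = 0.0002),
                       planted_effects = NULL,
                       length_peaks = c(22, 28),
                       adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                       adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                       seed = 1L) {
  names(class_fractions) <- sub("^repeat\\.$", "repeat", names(class_fractions))
  stopifnot(n_libraries >= 2, length(library_ids) == n_libraries,
            reads_per_library > 0, n_mirnas >= 1)
  if (!setequal(names(class_fractions), ANNOTATION_CLASSES))
    stop("class_fractions must be named by the annotation classes: ",
         paste(ANNOTATION_CLASSES, collapse = ", "))
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (!all(names(contamination_fractions) %in% FILTER_CATEGORIES))
    stop("unknown contamination category: ",
         paste(setdiff(names(contamination_fractions), FILTER_CATEGORIES),
               collapse = ", "))
  if (any(contamination_fractions < 0 | contamination_fractions >= 1))
    stop("contamination_fractions must each lie in [0, 1)")
  assert_dna(adapter_3p, "adapter_3p")
  assert_dna(adapter_5p, "adapter_5p")
  if (grepl("N", adapter_3p) || grepl("N", adapter_5p))
    stop("adapters must not contain N")
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("mirna_id", "library_id", "log2_fold_change") %in%
                    names(planted_effects)))
    if (any(!planted_effects$library_id %in% library_ids))
      stop("planted_effects refers to unknown library ids")
  }
  cf <- setNames(numeric(length(FILTER_CATEGORIES)), FILTER_CATEGORIES)
  cf[names(contamination_fractions)] <- contamination_fractions
  structure(list(n_libraries = n_libraries, library_ids = library_ids,
                 reads_per_library = reads_per_library, n_mirnas = n_mirnas,
                 class_fractions = class_fractions[ANNOTATION_CLASSES],
                 contamination_fractions = cf,
                 planted_effects = planted_effects,
                 length_peaks = as.integer(length_peaks),
                 adapter_3p = toupper(adapter_3p),
                 adapter_5p = toupper(adapter_5p),
                 seed = as.integer(seed)),
            class = "smrna_sim_config")
}

#' @export
print.smrna_sim_config <- function(x, ...) {
  cat("Synthetic small RNA study configuration\n")
  cat("  libraries:", paste(x$library_ids, collapse = ", "),
      sprintf("(~%d reads each)\n", x$reads_per_library))
  cat("  miRNAs:", x$n_mirnas,
      " | planted effects:", if (is.null(x$planted_effects)) 0
      else nrow(x$planted_effects), "\n")
  cat("  length peaks:", paste(x$length_peaks, collapse = "/"), "nt | seed:",
      x$seed, "\n")
  invisible(x)
}

# Build a hairpin precursor: mature arm + loop + (mismatched) reverse
# complement of the mature. The mature is an exact substring by construction.
make_precursor <- function(mature, loop_len = 10, n_mismatches = 2) {
  loop <- random_dna(1, loop_len)
  arm <- strsplit(revcomp(mature), "", fixed = TRUE)[[1]]
  if (n_mismatches > 0) {
    pos <- sample(seq_along(arm), min(n_mismatches, length(arm)))
    arm[pos] <- vapply(arm[pos],
                       function(b) sample(setdiff(DNA_BASES, b), 1),
                       character(1))
  }
  paste0(mature, loop, paste(arm, collapse = ""))
}

#' Generate the synthetic reference sets
#'
#' Builds mature and precursor miRNA references (precursors fold into a
#' stem-loop by construction), per-class reference sequences for the
#' structural RNA and genomic annotation classes, a concatenated synthetic
#' genome containing the precursors and class references, and the relative
#' abundance of each miRNA used by [generate_library()].
#'
#' @param config a [sim_config()] object.
#' @return a list of class `smrna_references` with elements `mature`,
#'   `precursor` (named character vectors), `classes` (list of named
#'   character vectors per annotation class), `genome` (single string) and
#'   `abundance` (named, sums to 1).
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "smrna_sim_config"))
  with_seed(config$seed, {
    n <- config$n_mirnas
    ids <- sprintf("sim-mir-%03d", seq_len(n))
    lens <- sample(as.integer(names(MIRNA_LEN_PROBS)), n, replace = TRUE,
                   prob = MIRNA_LEN_PROBS)
    mature <- setNames(random_dna(n, lens), ids)
    precursor <- setNames(
      vapply(mature, function(m)
        make_precursor(m, loop_len = sample(8:12, 1)), character(1)),
      sub("mir", "pre-mir", ids))
    abundance <- exp(rnorm(n, 0, 1))
    abundance <- setNames(abundance / sum(abundance), ids)
    classes <- list()
    for (cl in setdiff(ANNOTATION_CLASSES, c("miRNA", "unannotated"))) {
      k <- 3L
      classes[[cl]] <- setNames(random_dna(k, sample(200:600, k, TRUE)),
                                sprintf("%s-ref-%02d", cl, seq_len(k)))
    }
    genome <- paste(c(unname(precursor), unlist(unname(classes)),
                      random_dna(4, 500)),
                    collapse = "")
    structure(list(mature = mature, precursor = precursor, classes = classes,
                   genome = genome, abundance = abundance),
              class = "smrna_references")
  })
}

# Sample insert lengths around the configured peaks; the probability tables
# are shifted so the mode lands exactly on the configured peak.
sample_lengths <- function(n, probs, peak_default, peak) {
  lens <- as.integer(names(probs)) + (peak - peak_default)
  sample(lens, n, replace = TRUE, prob = probs)
}

# Random substrings of a set of reference sequences.
sample_fragments <- function(refs, n, lens) {
  idx <- sample(seq_along(refs), n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    s <- refs[[idx[i]]]
    l <- min(lens[i], nchar(s))
    start <- sample(nchar(s) - l + 1, 1)
    substr(s, start, start + l - 1)
  }, character(1)) -> frags
  list(fragments = frags, source = names(refs)[idx])
}

#' Simulate per-miRNA counts for a control/treatment pair
#'
#' Count-level generator used for power and type-I studies of the exact
#' test: counts are independent Poisson draws with mean
#' `tpm / 1e6 * depth`, the treatment mean scaled by `2^log2_fold_change`.
#'
#' @param base_tpm numeric vector of true control-library TPM per miRNA.
#' @param log2_fold_change numeric vector (recycled) of planted effects.
#' @param depth_control,depth_treatment library clean-read totals.
#' @param seed optional integer seed.
#' @return data frame with `mirna_id`, `count_control`, `count_treatment`,
#'   `true_log2fc`.
#' @export
simulate_mirna_counts <- function(base_tpm, log2_fold_change = 0,
                                  depth_control = 1e6, depth_treatment = 1e6,
                                  seed = NULL) {
  stopifnot(all(base_tpm >= 0), depth_control > 0, depth_treatment > 0)
  lfc <- rep_len(log2_fold_change, length(base_tpm))
  draw <- function() {
    mu_c <- base_tpm / 1e6 * depth_control
    mu_t <- base_tpm * 2^lfc / 1e6 * depth_treatment
    data.frame(mirna_id = sprintf("sim-mir-%03d", seq_along(base_tpm)),
               count_control = rpois(length(mu_c), mu_c),
               count_treatment = rpois(length(mu_t), mu_t),
               true_log2fc = lfc,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate one synthetic sequencing library
#'
#' Draws reads for one library: clean inserts from the configured
#' annotation-class mixture (miRNA reads are exact mature sequences with
#' Poisson counts, other classes are reference fragments with piRNA-sized
#' lengths), plus the configured fractions of each removal category. All
#' reads except the 3' adapter-null fraction carry the 3' adapter. Planted
#' effects scale the expected miRNA counts by `2^log2_fold_change` in the
#' named library.
#'
#' @param config a [sim_config()] object.
#' @param refs references from [generate_references()].
#' @param library_id one of `config$library_ids`.
#' @return list of class `smrna_library` with elements `library_id`,
#'   `reads` (a [Biostrings::QualityScaledDNAStringSet]), `truth` (data
#'   frame: read_id, category, source_id) and `expected_mirna_counts`
#'   (data frame: mirna_id, expected_count).
#' @export
generate_library <- function(config, refs, library_id) {
  stopifnot(inherits(config, "smrna_sim_config"),
            inherits(refs, "smrna_references"))
  lib_idx <- match(library_id, config$library_ids)
  if (is.na(lib_idx)) stop("unknown library id: ", library_id)
  pe <- config$planted_effects
  if (!is.null(pe)) {
    missing <- setdiff(pe$mirna_id, names(refs$mature))
    if (length(missing) > 0)
      stop("planted miRNA id not in references: ",
           paste(missing, collapse = ", "))
  }
  with_seed(config$seed + 7919L * lib_idx, {
    total <- config$reads_per_library
    cfrac <- config$contamination_fractions
    clean_target <- total * (1 - sum(cfrac))
    peaks <- config$length_peaks
    ad3 <- config$adapter_3p
    ad5 <- config$adapter_5p

    # expected miRNA counts (Poisson means), with planted effects applied
    lfc <- setNames(numeric(length(refs$mature)), names(refs$mature))
    if (!is.null(pe) && lib_idx > 1) {
      sel <- pe$library_id == library_id
      lfc[pe$mirna_id[sel]] <- pe$log2_fold_change[sel]
    }
    mu <- clean_target * config$class_fractions[["miRNA"]] *
      refs$abundance * 2^lfc
    mirna_counts <- rpois(length(mu), mu)

    inserts <- rep(names(refs$mature), mirna_counts)
    seqs <- unname(refs$mature[inserts])
    category <- rep("miRNA", length(seqs))
    source <- inserts

    for (cl in setdiff(ANNOTATION_CLASSES, c("miRNA", "unannotated"))) {
      k <- rpois(1, clean_target * config$class_fractions[[cl]])
      if (k == 0) next
      lens <- sample_lengths(k, PIRNA_LEN_PROBS, 28L, peaks[2])
      fr <- sample_fragments(refs$classes[[cl]], k, lens)
      seqs <- c(seqs, fr$fragments)
      category <- c(category, rep(cl, k))
      source <- c(source, fr$source)
    }
    k <- rpois(1, clean_target * config$class_fractions[["unannotated"]])
    if (k > 0) {
      lens <- sample_lengths(k, PIRNA_LEN_PROBS, 28L, peaks[2])
      seqs <- c(seqs, random_dna(k, lens))
      category <- c(category, rep("unannotated", k))
      source <- c(source, rep("", k))
    }
    reads <- paste0(seqs, ad3)
    qual <- rep("high", length(reads))

    # removal categories
    add <- function(r, cat, q = "high", src = "") {
      reads <<- c(reads, r)
      category <<- c(category, rep(cat, length(r)))
      source <<- c(source, rep(src, length(r)))
      qual <<- c(qual, rep(q, length(r)))
    }
    n_cat <- setNames(rpois(length(cfrac), total * cfrac), names(cfrac))
    if (n_cat[["low_quality"]] > 0)
      add(paste0(random_dna(n_cat[["low_quality"]], 18:25), ad3),
          "low_quality", q = "low")
    if (n_cat[["three_prime_adapter_null"]] > 0) {
      ad6 <- substr(ad3, 1, 6)
      r <- vapply(seq_len(n_cat[["three_prime_adapter_null"]]), function(i) {
        repeat {
          s <- random_dna(1, sample(30:40, 1))
          if (!grepl(ad6, s, fixed = TRUE)) return(s)
        }
      }, character(1))
      add(r, "three_prime_adapter_null")
    }
    if (n_cat[["insert_null"]] > 0)
      add(paste0(ad3, random_dna(n_cat[["insert_null"]], 8)), "insert_null")
    if (n_cat[["five_prime_contaminant"]] > 0)
      add(paste0(substr(ad5, 1, 10),
                 random_dna(n_cat[["five_prime_contaminant"]], 18:24), ad3),
          "five_prime_contaminant")
    if (n_cat[["shorter_than_18"]] > 0)
      add(paste0(random_dna(n_cat[["shorter_than_18"]], 8:17), ad3),
          "shorter_than_18")
    if (n_cat[["polyA"]] > 0) {
      pa <- vapply(sample(18:24, n_cat[["polyA"]], TRUE), function(l) {
        b <- rep("A", l)                       # >= 90% A by construction
        k_non <- floor(l * 0.1)
        if (k_non > 0)
          b[sample(l, k_non)] <- sample(c("C", "G", "T"), k_non, TRUE)
        paste(b, collapse = "")
      }, character(1))
      add(paste0(pa, ad3), "polyA")
    }

    ord <- sample(length(reads))
    reads <- reads[ord]; category <- category[ord]
    source <- source[ord]; qual <- qual[ord]
    ids <- sprintf("%s_read%07d", library_id, seq_along(reads))
    widths <- nchar(reads)
    qstr <- vapply(seq_along(reads), function(i) {
      if (qual[i] == "high") strrep("I", widths[i])          # Phred 40
      else strrep("+", widths[i])                            # Phred 10
    }, character(1))
    qsr <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(reads, ids)),
      Biostrings::PhredQuality(qstr))
    structure(list(
      library_id = library_id,
      reads = qsr,
      truth = data.frame(read_id = ids, category = category,
                         source_id = source, stringsAsFactors = FALSE),
      expected_mirna_counts = data.frame(mirna_id = names(refs$mature),
                                         expected_count = unname(mu),
                                         stringsAsFactors = FALSE)),
      class = "smrna_library")
  })
}

#' Generate the whole synthetic study
#'
#' @param config a [sim_config()] object.
#' @return list with `references` and `libraries` (one [generate_library()]
#'   result per configured library).
#' @export
generate_study <- function(config) {
  refs <- generate_references(config)
  libs <- lapply(config$library_ids, function(id)
    generate_library(config, refs, id))
  names(libs) <- config$library_ids
  list(references = refs, libraries = libs)
}

#' Write reference FASTA files
#'
#' @param refs from [generate_references()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_references <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  sets <- c(list(mature = refs$mature, precursor = refs$precursor),
            refs$classes)
  for (nm in names(sets)) {
    p <- file.path(dir, paste0(nm, ".fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sets[[nm]]), p)
    out <- c(out, p)
  }
  p <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(refs$genome, "synthetic_genome")), p)
  invisible(c(out, p))
}

#' Write a synthetic library as FASTQ plus its truth table
#'
#' @param lib from [generate_library()].
#' @param dir output directory.
#' @return invisibly, the FASTQ path.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, paste0(lib$library_id, ".fastq"))
  Biostrings::writeQualityScaledXStringSet(lib$reads, fq)
  write_tsv(lib$truth, file.path(dir, paste0(lib$library_id, "_truth.tsv")))
  invisible(fq)
}
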