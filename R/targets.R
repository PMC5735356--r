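# Target prediction stand-in and predictor-set intersection.
#
# Real studies run several target predictors and keep the pairs called by
# all of them. The runnable stand-in here is a classical seed match: a
# (miRNA, transcript) pair is predicted when the reverse complement of the
# miRNA seed (positions 2-8) occurs in the transcript 3' UTR. Intersection
# logic operates on (mirna_id, transcript_id) identities regardless of
# which predictor produced them.

#' Seed-match target prediction
#'
#' Emits a pair when the reverse complement of miRNA positions 2-8 (the
#' 7-mer seed) occurs in the 3' UTR; `site_position` is the 0-based
#' position of the first such site on the transcript.
#'
#' @param mirnas named character vector of mature miRNA sequences (RNA or
#'   DNA).
#' @param utrs named character vector of transcript 3' UTR sequences (DNA).
#' @return data frame (`mirna_id`, `transcript_id`, `site_position`).
#' @export
seed_match_predict <- function(mirnas, utrs) {
  stopifnot(!is.null(names(mirnas)))
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_position = integer(0))
  if (length(utrs) == 0) return(empty)
  stopifnot(!is.null(names(utrs)))
  seeds <- revcomp(substr(rna_to_dna(mirnas), 2, 8))
  short <- nchar(seeds) < 7
  if (any(short))
    warning("miRNA(s) shorter than 8 nt skipped: ",
            paste(names(mirnas)[short], collapse = ", "))
  rows <- lapply(which(!short), function(i) {
    pos <- vapply(utrs, function(u)
      regexpr(seeds[i], rna_to_dna(u), fixed = TRUE)[1], integer(1))
    hit <- pos > 0
    if (!any(hit)) return(NULL)
    data.frame(mirna_id = names(mirnas)[i],
               transcript_id = names(utrs)[hit],
               site_position = unname(pos[hit]) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

pair_keys <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("mirna_id", "transcript_id") %in% names(x)))
    unique(paste(x$mirna_id, x$transcript_id, sep = "\r"))
  } else unique(as.character(x))
}

#' Three-way intersection of predictor target sets
#'
#' Counts the seven regions of the three-set Venn diagram over
#' (mirna_id, transcript_id) identities (site positions are ignored) and
#' returns the pairs common to all three predictors.
#'
#' @param a,b,c target sets: data frames with `mirna_id` and
#'   `transcript_id` columns, or character vectors of identities.
#' @return list with `regions` (named counts: a_only, b_only, c_only,
#'   ab_only, ac_only, bc_only, abc), `pairwise` (|A&B|, |A&C|, |B&C|),
#'   `union_size` and `common` (data frame of pairs in all three).
#' @export
venn_intersections <- function(a, b, c) {
  ka <- pair_keys(a); kb <- pair_keys(b); kc <- pair_keys(c)
  all_keys <- unique(c(ka, kb, kc))
  ia <- all_keys %in% ka; ib <- all_keys %in% kb; ic <- all_keys %in% kc
  regions <- c(
    a_only = sum(ia & !ib & !ic), b_only = sum(!ia & ib & !ic),
    c_only = sum(!ia & !ib & ic), ab_only = sum(ia & ib & !ic),
    ac_only = sum(ia & !ib & ic), bc_only = sum(!ia & ib & ic),
    abc = sum(ia & ib & ic))
  common_keys <- all_keys[ia & ib & ic]
  parts <- strsplit(common_keys, "\r", fixed = TRUE)
  common <- data.frame(
    mirna_id = vapply(parts, `[`, character(1), 1),
    transcript_id = vapply(parts, function(p)
      if (length(p) > 1) p[2] else NA_character_, character(1)),
    stringsAsFactors = FALSE)
  list(regions = regions,
       pairwise = c(ab = sum(ia & ib), ac = sum(ia & ic),
                    bc = sum(ib & ic)),
       union_size = length(all_keys),
       common = common)
}
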