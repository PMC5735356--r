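# Packaged reference tables from a published five-library P. xylostella
# small RNA infection time course (Tween control plus 12/18/24/36 h
# post-infection). These carry the printed per-library filter accounting,
# the top-abundance miRNA counts, the differential expression surface
# (TPM pairs with fold-changes and corrected p-values), and the
# genome-mapping totals; they serve as worked numeric examples for the
# accounting, normalization and fold-change operations.

study_table <- function(name) {
  path <- system.file("extdata", name, package = "smrnade",
                      mustWork = TRUE)
  read_tsv(path)
}

#' Published per-library filter accounting
#'
#' Per-category read counts and printed percentages for five small RNA
#' libraries (control plus four infection time points). Percentages are
#' relative to the high-quality total of each library.
#'
#' @return data frame (`library`, `category`, `count`, `percent`).
#' @export
study_accounting <- function() study_table("study_filter_accounting.tsv")

#' Published differential expression surface
#'
#' The five miRNAs differentially expressed at both early time points:
#' control and treatment TPM, log2 fold-change, exact-test p-value and
#' Bonferroni-corrected value (printed as FDR).
#'
#' @return data frame (`mirna_id`, `treatment`, `control_tpm`,
#'   `treatment_tpm`, `log2fc`, `pvalue`, `fdr`).
#' @export
study_de_tpm <- function() study_table("study_de_tpm.tsv")

#' Published top-10 abundant miRNA counts
#'
#' Counts of the ten most abundant miRNAs common to all five libraries,
#' with mature sequences.
#'
#' @return data frame (`mirna_id`, `sequence`, one count column per
#'   library).
#' @export
study_top_counts <- function() study_table("study_top_counts.tsv")

#' Published genome-mapping totals
#'
#' Mapped and clean read totals per library with the printed mapped
#' percentage.
#'
#' @return data frame (`library`, `mapped_reads`, `clean_reads`,
#'   `percent`).
#' @export
study_genome_mapping <- function() study_table("study_genome_mapping.tsv")
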