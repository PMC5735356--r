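# TPM normalization and the exact count-based differential expression test.
#
# The test compares one miRNA's counts x (control) and y (treatment) given
# the library clean-read totals N1 and N2, using the exact
# (Audic-Claverie-type) conditional probability
#
#   p(y | x) = (N2/N1)^y * (x+y)! / (x! y!) / (1 + N2/N1)^(x+y+1)
#
# evaluated in log-gamma space. The two-tailed p-value is
# 2 * min(P(Y <= y | x), P(Y >= y | x)), capped at 1; both tails include
# the observed y. Multiple testing within a pairwise comparison is
# corrected by Bonferroni.

#' Transcripts-per-million normalization
#'
#' `tpm = 1e6 * count / total_clean` — the miRNA count scaled by the
#' library's clean-read total.
#'
#' @param count miRNA count(s), non-negative.
#' @param total_clean library clean-read total (> 0).
#' @return numeric TPM value(s).
#' @export
tpm <- function(count, total_clean) {
  if (any(total_clean <= 0)) stop("total_clean must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  1e6 * count / total_clean
}

#' Apply the zero and low-expression rules to a TPM matrix
#'
#' Zeros are replaced by 0.01 (so ratios remain computable) and rows whose
#' normalized expression is below 1 TPM in every library are dropped.
#'
#' @param x numeric matrix (rows = miRNAs, columns = libraries), row names
#'   are miRNA ids.
#' @param low_threshold drop rows entirely below this TPM (default 1).
#' @return the filtered matrix with no zero entries.
#' @export
apply_zero_and_low_rules <- function(x, low_threshold = 1) {
  x <- as.matrix(x)
  x[x == 0] <- 0.01
  keep <- apply(x, 1, function(r) any(r >= low_threshold))
  x[keep, , drop = FALSE]
}

#' Log2 fold-change of treatment over control
#'
#' @param tpm_treatment,tpm_control positive normalized expressions (apply
#'   the zero rule first).
#' @return `log2(tpm_treatment / tpm_control)`.
#' @export
log2_fold_change <- function(tpm_treatment, tpm_control) {
  if (any(tpm_treatment <= 0) || any(tpm_control <= 0))
    stop("fold-change requires positive TPM; apply the zero rule first")
  log2(tpm_treatment / tpm_control)
}

ac_log_pmf <- function(y, x, ratio) {
  y * log(ratio) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(ratio)
}

#' Exact-test probability mass p(y | x)
#'
#' The conditional probability of observing count `y` in the second library
#' given `x` in the first, with library-size ratio `N2/N1`; a negative
#' binomial in form, evaluated in log space.
#'
#' @param y,x non-negative integer counts.
#' @param ratio `N2 / N1`, the ratio of clean-read totals (> 0).
#' @return probability in (0, 1]; sums to 1 over `y` at fixed `x`.
#' @export
ac_pmf <- function(y, x, ratio = 1) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(ratio <= 0)) stop("ratio must be positive")
  exp(ac_log_pmf(y, x, ratio))
}

#' Two-tailed exact-test p-value for a count pair
#'
#' Lower tail `C = P(Y <= y | x)` and upper tail `D = P(Y >= y | x)` are
#' combined as `p = min(1, 2 * min(C, D))`; both tails include the observed
#' `y`.
#'
#' @param x,y miRNA counts in control and treatment.
#' @param N1,N2 clean-read totals of the two libraries.
#' @return p-value in (0, 1]. Vectorised over `x`, `y`.
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) {
    r <- N2[i] / N1[i]
    lower <- sum(exp(ac_log_pmf(0:y[i], x[i], r)))
    upper <- 1 - lower + exp(ac_log_pmf(y[i], x[i], r))
    min(1, 2 * min(lower, max(upper, 0)))
  }, numeric(1))
}

#' Bonferroni multiple-testing correction
#'
#' `adjusted = min(1, m * p)` with `m` the number of tests in the
#' comparison. (Reported under the column name `fdr` in output tables for
#' compatibility with the usual table layout, although the method is
#' Bonferroni.)
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "bonferroni")
}

#' Differential expression call parameters
#'
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param min_abs_log2fc minimum absolute log2 fold-change (default 1).
#' @param low_expression_threshold TPM below which a miRNA is ignored when
#'   below it in every library (default 1).
#' @return parameter list.
#' @export
de_params <- function(alpha = 0.05, min_abs_log2fc = 1,
                      low_expression_threshold = 1) {
  stopifnot(alpha > 0, alpha < 1, min_abs_log2fc >= 0)
  list(alpha = alpha, min_abs_log2fc = min_abs_log2fc,
       low_expression_threshold = low_expression_threshold)
}

#' Pairwise differential expression table
#'
#' Normalizes the count table to TPM, applies the zero and low-expression
#' rules across all libraries, then for the chosen control/treatment pair
#' computes log2 fold-changes, exact-test p-values from the raw counts, and
#' Bonferroni-adjusted p-values over the retained miRNAs of this
#' comparison. A miRNA is called significant when `fdr < alpha` and
#' `|log2fc| >= min_abs_log2fc`.
#'
#' @param counts data frame with column `mirna_id` plus one integer count
#'   column per library.
#' @param control,treatment library column names.
#' @param totals named numeric vector of clean-read totals, covering every
#'   count column.
#' @param params see [de_params()].
#' @return data frame with columns `mirna_id`, `tpm_control`,
#'   `tpm_treatment`, `log2fc`, `pvalue`, `fdr`, `significant`.
#' @export
de_table <- function(counts, control, treatment, totals,
                     params = de_params()) {
  stopifnot(is.data.frame(counts), "mirna_id" %in% names(counts))
  libs <- setdiff(names(counts), "mirna_id")
  if (!all(c(control, treatment) %in% libs))
    stop("control/treatment must name count columns")
  if (!all(libs %in% names(totals)))
    stop("totals must cover every library column")
  if (any(totals[libs] <= 0)) stop("library totals must be positive")
  cm <- as.matrix(counts[libs])
  rownames(cm) <- counts$mirna_id
  tpm_mat <- sweep(cm, 2, as.numeric(totals[libs]), function(c, n) tpm(c, n))
  tpm_mat <- apply_zero_and_low_rules(tpm_mat,
                                      params$low_expression_threshold)
  keep <- rownames(tpm_mat)
  x <- cm[keep, control]
  y <- cm[keep, treatment]
  lfc <- log2_fold_change(tpm_mat[, treatment], tpm_mat[, control])
  p <- ac_pvalue(x, y, totals[[control]], totals[[treatment]])
  fdr <- bonferroni(p)
  out <- data.frame(mirna_id = keep,
                    tpm_control = unname(tpm_mat[, control]),
                    tpm_treatment = unname(tpm_mat[, treatment]),
                    log2fc = unname(lfc), pvalue = p, fdr = fdr,
                    significant = fdr < params$alpha &
                      abs(lfc) >= params$min_abs_log2fc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Volcano-plot table
#'
#' @param de data frame from [de_table()].
#' @return data frame (`mirna_id`, `log2fc`, `neg_log10_fdr`, `call`).
#' @export
volcano_table <- function(de) {
  data.frame(mirna_id = de$mirna_id, log2fc = de$log2fc,
             neg_log10_fdr = -log10(pmax(de$fdr, 1e-300)),
             call = ifelse(de$significant,
                           ifelse(de$log2fc > 0, "up", "down"), "ns"),
             stringsAsFactors = FALSE)
}

#' Top-N most abundant miRNAs common to all libraries
#'
#' Restricted to miRNAs with a nonzero count in every library, ranked by
#' the control-library count (descending, lexicographic tie-break).
#'
#' @param counts data frame with `mirna_id` plus count columns.
#' @param control control-library column name used for ranking.
#' @param n number of rows to keep.
#' @return the ranked subset of `counts`.
#' @export
top_n_abundant <- function(counts, control, n = 10) {
  stopifnot(n >= 1, "mirna_id" %in% names(counts),
            control %in% names(counts))
  libs <- setdiff(names(counts), "mirna_id")
  common <- counts[apply(counts[libs] > 0, 1, all), , drop = FALSE]
  common <- common[order(-common[[control]], common$mirna_id), ,
                   drop = FALSE]
  rownames(common) <- NULL
  head(common, n)
}

#' Aggregate tag counts to mature miRNA counts
#'
#' Sums the counts of every tag assigned to each mature miRNA (isomiR
#' tolerance as in [classify_tags()]); the unit of the exact test is the
#' mature miRNA, not the individual tag.
#'
#' @param tags tag data frame (`sequence`, `count`).
#' @param mature named character vector of mature miRNA sequences.
#' @param offset_tolerance isomiR length tolerance in nt (default 2).
#' @return data frame (`mirna_id`, `count`) covering every mature miRNA.
#' @export
mirna_counts <- function(tags, mature, offset_tolerance = 2L) {
  mature <- rna_to_dna(load_sequences(mature, "mature"))
  counts <- vapply(seq_along(mature), function(i) {
    m <- mature[i]; ml <- nchar(m)
    l <- nchar(tags$sequence)
    cand <- abs(l - ml) <= offset_tolerance
    hit <- cand
    hit[cand] <- vapply(which(cand), function(j) {
      s <- tags$sequence[j]
      if (nchar(s) <= ml) grepl(s, m, fixed = TRUE)
      else grepl(m, s, fixed = TRUE)
    }, logical(1))
    sum(tags$count[hit])
  }, numeric(1))
  data.frame(mirna_id = names(mature), count = as.integer(counts),
             stringsAsFactors = FALSE)
}
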