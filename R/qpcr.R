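# Relative quantification by the 2^-ddCt method and concordance with
# sequencing fold-changes.
#
# Per condition, dCt = Ct(target) - Ct(reference gene, e.g. U6 snRNA),
# averaged over replicates on the Ct scale; ddCt = dCt(treatment) -
# dCt(control); relative expression = 2^-ddCt. The replicate SD of dCt is
# propagated to the reported error.

#' Relative expression by 2^-ddCt
#'
#' @param ct data frame with columns `target_id`, `condition` ("control" or
#'   "treatment"), `replicate`, `ct_target`, `ct_reference`.
#' @return data frame per target: `dct_control`, `dct_treatment`, `ddct`,
#'   `fold` (2^-ddct), `log2_fold` (= -ddct) and `sd_ddct` (propagated
#'   replicate SD, NA with single replicates).
#' @export
ddct_fold <- function(ct) {
  need <- c("target_id", "condition", "replicate", "ct_target",
            "ct_reference")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  if (!all(ct$condition %in% c("control", "treatment")))
    stop("condition must be 'control' or 'treatment'")
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45 |
          ct$ct_reference <= 0 | ct$ct_reference >= 45))
    stop("Ct values must lie in (0, 45)")
  ct$dct <- ct$ct_target - ct$ct_reference
  rows <- lapply(split(ct, ct$target_id), function(d) {
    for (cond in c("control", "treatment"))
      if (!any(d$condition == cond))
        stop("target ", d$target_id[1], " lacks the ", cond, " condition")
    dc <- d$dct[d$condition == "control"]
    dt <- d$dct[d$condition == "treatment"]
    ddct <- mean(dt) - mean(dc)
    data.frame(target_id = d$target_id[1],
               dct_control = mean(dc), dct_treatment = mean(dt),
               ddct = ddct, fold = 2^-ddct, log2_fold = -ddct,
               sd_ddct = sqrt(stats::var(dc) + stats::var(dt)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sign concordance between qPCR and sequencing fold-changes
#'
#' A target agrees when the sign of its qPCR log2 fold equals the sign of
#' its sequencing log2 fold-change.
#'
#' @param qpcr data frame from [ddct_fold()] (needs `target_id`,
#'   `log2_fold`).
#' @param sequencing data frame with `mirna_id` and `log2fc` (e.g. from
#'   [de_table()]).
#' @return list with `per_target` (data frame: target_id, qpcr_log2fc,
#'   seq_log2fc, agree) and `fraction` of agreeing targets.
#' @export
concordance <- function(qpcr, sequencing) {
  stopifnot(all(c("target_id", "log2_fold") %in% names(qpcr)),
            all(c("mirna_id", "log2fc") %in% names(sequencing)))
  shared <- intersect(qpcr$target_id, sequencing$mirna_id)
  if (length(shared) == 0) stop("no shared target ids")
  q <- qpcr[match(shared, qpcr$target_id), ]
  s <- sequencing[match(shared, sequencing$mirna_id), ]
  agree <- sign(q$log2_fold) == sign(s$log2fc)
  list(per_target = data.frame(target_id = shared,
                               qpcr_log2fc = q$log2_fold,
                               seq_log2fc = s$log2fc, agree = agree,
                               stringsAsFactors = FALSE),
       fraction = mean(agree))
}
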