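# Novel miRNA candidate filtering.
#
# Candidates (hairpin precursors with an externally produced discovery
# score) are accepted when all three criteria hold: discovery score > 1,
# shuffle-test p-value < 0.05, and folding energy < -19 kcal/mol.
#
# The shuffle test asks whether the candidate folds with lower energy than
# dinucleotide-preserving shuffles of itself (randfold-style). Shuffling
# uses the Euler-path construction (Altschul-Erickson): the sequence is a
# walk on the base graph whose edges are its dinucleotides, and a random
# Eulerian path with the same edge multiset is an exact
# dinucleotide-preserving permutation with the first and last base fixed.
#
# The default folding energy is a deliberately simple, fully documented
# model (see `rna_energy_model()`): additive base-pair energies plus a
# stacking bonus for directly nested pairs, over nested (pseudoknot-free)
# structures with a minimum hairpin loop of 3, minimised exactly by dynamic
# programming. The scorer is pluggable; the -19 kcal/mol acceptance
# threshold is meaningful relative to the configured model.

#' Simple RNA folding energy model
#'
#' Pair energies in kcal/mol: GC/CG -3, AU/UA -2, GU/UG -1; a stacking
#' bonus (default -1) for each pair whose directly enclosed neighbour is
#' also paired; minimum hairpin loop of `min_loop` unpaired bases.
#'
#' @param pair_energies named numeric vector over the canonical pairs.
#' @param stack_bonus energy added per stacked pair (<= 0).
#' @param min_loop minimum unpaired bases in a hairpin loop.
#' @return model list consumed by [fold_energy()] and [score_structure()].
#' @export
rna_energy_model <- function(pair_energies = c(GC = -3, CG = -3, AU = -2,
                                               UA = -2, GU = -1, UG = -1),
                             stack_bonus = -1, min_loop = 3L) {
  stopifnot(all(pair_energies <= 0), stack_bonus <= 0, min_loop >= 0)
  list(pair_energies = pair_energies, stack_bonus = stack_bonus,
       min_loop = as.integer(min_loop))
}

rna_bases <- function(sequence) {
  s <- dna_to_rna(sequence)
  if (grepl("[^ACGU]", s))
    stop("invalid RNA alphabet in sequence: ", sequence)
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' Energy of a given secondary structure
#'
#' Scores an explicit set of base pairs under the model: the sum of pair
#' energies plus the stacking bonus for each pair directly enclosing
#' another pair. Used both by the folding optimiser and by exhaustive
#' enumeration.
#'
#' @param sequence RNA (or DNA; T is read as U) string.
#' @param pairs two-column matrix of paired positions (i < j), possibly
#'   with zero rows.
#' @param model see [rna_energy_model()].
#' @return energy in kcal/mol (0 for the empty structure).
#' @export
score_structure <- function(sequence, pairs, model = rna_energy_model()) {
  b <- rna_bases(sequence)
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  pe <- model$pair_energies[paste0(b[pairs[, 1]], b[pairs[, 2]])]
  if (any(is.na(pe)))
    stop("structure contains a non-canonical pair")
  key <- paste(pairs[, 1], pairs[, 2])
  stacked <- paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% key
  sum(pe) + model$stack_bonus * sum(stacked)
}

#' Minimum folding energy over nested structures
#'
#' Exact minimisation of the model energy over all pseudoknot-free
#' structures by dynamic programming: `V[i,j]` is the best energy with
#' `(i,j)` paired (taking the stacking bonus when the enclosed pair
#' `(i+1,j-1)` is formed), `W[i,j]` the best energy on the subsequence,
#' including bifurcations.
#'
#' @param sequence RNA (or DNA) string.
#' @param model see [rna_energy_model()].
#' @return minimum energy in kcal/mol (<= 0).
#' @export
fold_energy <- function(sequence, model = rna_energy_model()) {
  b <- rna_bases(sequence)
  n <- length(b)
  min_span <- model$min_loop + 1L
  if (n < min_span + 1L) return(0)
  pe_of <- function(i, j) {
    e <- model$pair_energies[paste0(b[i], b[j])]
    if (is.na(e)) NA_real_ else unname(e)
  }
  V <- matrix(Inf, n, n)
  W <- matrix(0, n, n)
  for (span in min_span:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      pe <- pe_of(i, j)
      if (!is.na(pe)) {
        v <- pe + W[i + 1L, j - 1L]
        if (j - i - 2L >= min_span && is.finite(V[i + 1L, j - 1L]))
          v <- min(v, pe + model$stack_bonus + V[i + 1L, j - 1L])
        V[i, j] <- v
      }
      w <- min(W[i + 1L, j], W[i, j - 1L], V[i, j])
      ks <- i:(j - 1L)
      w <- min(w, min(W[i, ks] + W[cbind(ks + 1L, j)]))
      W[i, j] <- w
    }
  }
  W[1L, n]
}

#' Dinucleotide-preserving shuffle
#'
#' Returns a random permutation of the sequence with an identical multiset
#' of overlapping dinucleotides (hence identical mononucleotide
#' composition) and the first and last base preserved, via a random
#' Eulerian path on the dinucleotide graph (Hierholzer's algorithm with
#' randomised edge order).
#'
#' @param sequence string of length >= 3.
#' @param seed optional integer seed for a reproducible shuffle.
#' @return shuffled sequence (same alphabet case-normalised to the input
#'   alphabet family: RNA in, RNA out).
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  was_rna <- grepl("U", toupper(sequence), fixed = TRUE)
  s <- toupper(rna_to_dna(sequence))
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(b) < 3) stop("sequence must be at least 3 nt to shuffle")
  run <- function() {
    verts <- unique(b)
    adj <- lapply(setNames(verts, verts), function(v)
      sample(b[which(b[-length(b)] == v) + 1L]))
    ptr <- setNames(rep(1L, length(verts)), verts)
    stack <- b[1]
    path <- character(0)
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      if (ptr[[v]] <= length(adj[[v]])) {
        u <- adj[[v]][ptr[[v]]]
        ptr[[v]] <- ptr[[v]] + 1L
        stack <- c(stack, u)
      } else {
        path <- c(path, v)
        stack <- stack[-length(stack)]
      }
    }
    paste(rev(path), collapse = "")
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  if (was_rna) dna_to_rna(out) else out
}

#' Empirical shuffle-test p-value for folding energy
#'
#' `p = (1 + k) / (1 + n_shuffles)` where `k` counts shuffles folding at
#' least as low as the candidate; the add-one form avoids p = 0 and is the
#' usual permutation-test estimator.
#'
#' @param sequence candidate precursor (RNA or DNA).
#' @param n_shuffles number of dinucleotide-preserving shuffles (>= 19,
#'   else p < 0.05 is unreachable).
#' @param seed integer seed.
#' @param model see [rna_energy_model()].
#' @return list with `pvalue`, `mfe` (candidate energy) and
#'   `shuffle_mfe` (vector of shuffle energies).
#' @export
randfold_pvalue <- function(sequence, n_shuffles = 99, seed = 1,
                            model = rna_energy_model()) {
  if (n_shuffles < 19)
    stop("n_shuffles must be >= 19 to resolve p < 0.05")
  mfe <- fold_energy(sequence, model)
  sh <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i)
      fold_energy(dinucleotide_shuffle(sequence), model), numeric(1))
  })
  list(pvalue = (1 + sum(sh <= mfe)) / (1 + n_shuffles),
       mfe = mfe, shuffle_mfe = sh)
}

#' Apply the novel miRNA acceptance criteria
#'
#' Accept iff `discovery_score > 1` and `randfold_p < 0.05` and
#' `mfe < -19` kcal/mol; the rejection reason names the first failed
#' criterion (score, then shuffle test, then energy).
#'
#' @param candidates data frame with columns `id`, `discovery_score`,
#'   `mfe`, `randfold_p`.
#' @param score_min,p_max,mfe_max the three thresholds.
#' @return the input with `decision` ("accept"/"reject") and `reason`
#'   columns added.
#' @export
apply_criteria <- function(candidates, score_min = 1, p_max = 0.05,
                           mfe_max = -19) {
  need <- c("id", "discovery_score", "mfe", "randfold_p")
  missing <- setdiff(need, names(candidates))
  if (length(missing) > 0)
    stop("candidates missing field(s): ", paste(missing, collapse = ", "))
  if (any(is.na(candidates[need])))
    stop("candidates contain missing values")
  reason <- rep("", nrow(candidates))
  fail_score <- !(candidates$discovery_score > score_min)
  fail_p <- !(candidates$randfold_p < p_max)
  fail_mfe <- !(candidates$mfe < mfe_max)
  reason[fail_mfe] <- "mfe"
  reason[fail_p] <- "randfold"
  reason[fail_score] <- "score"
  candidates$decision <- ifelse(reason == "", "accept", "reject")
  candidates$reason <- reason
  candidates
}

#' Score and filter candidate precursors end to end
#'
#' Computes the folding energy (unless supplied) and the shuffle-test
#' p-value for each candidate, then applies the acceptance criteria.
#'
#' @param sequences named character vector of candidate precursors.
#' @param discovery_scores named numeric vector (external tool scores).
#' @param n_shuffles,seed,model see [randfold_pvalue()].
#' @param mfe optional named numeric vector of precomputed energies.
#' @return decision data frame (`id`, `discovery_score`, `mfe`,
#'   `randfold_p`, `decision`, `reason`).
#' @export
filter_candidates <- function(sequences, discovery_scores, n_shuffles = 99,
                              seed = 1, model = rna_energy_model(),
                              mfe = NULL) {
  ids <- names(sequences)
  stopifnot(!is.null(ids), all(ids %in% names(discovery_scores)))
  rows <- lapply(seq_along(sequences), function(i) {
    rf <- randfold_pvalue(sequences[[i]], n_shuffles, seed + i - 1L, model)
    data.frame(id = ids[i],
               discovery_score = unname(discovery_scores[[ids[i]]]),
               mfe = if (!is.null(mfe)) unname(mfe[[ids[i]]]) else rf$mfe,
               randfold_p = rf$pvalue, stringsAsFactors = FALSE)
  })
  apply_criteria(do.call(rbind, rows))
}
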