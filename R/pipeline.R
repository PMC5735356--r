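# Pipeline orchestration and reproducible configuration.
#
# One entry point runs the stages in order on a synthetic study (or on
# user-provided FASTQ): simulate -> preprocess -> annotate -> de ->
# novel -> targets -> qpcr. Any stage can be skipped; a stage whose
# prerequisite was skipped fails with an error naming both. Logging goes to
# stderr; results go to TSV/FASTA/FASTQ files under the output directory.

PIPELINE_STAGES <- c("simulate", "preprocess", "annotate", "de", "novel",
                     "targets", "qpcr")

#' Pipeline configuration
#'
#' A plain-list configuration that round-trips losslessly through YAML
#' (see [write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed global integer seed.
#' @param stages character subset of
#'   `c("simulate","preprocess","annotate","de","novel","targets","qpcr")`.
#' @param sim named list of [sim_config()] overrides (e.g.
#'   `reads_per_library`, `n_mirnas`, `planted_effects` as a data frame or
#'   list of records).
#' @param de named list: `alpha`, `min_abs_log2fc`.
#' @param novel named list: `n_candidates`, `n_decoys`, `n_shuffles`.
#' @param targets named list: `n_transcripts`, `utr_length`.
#' @param qpcr named list: `n_targets`, `replicates`, `ct_sd`.
#' @param log_level "info" or "quiet".
#' @return list of class `smrna_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = PIPELINE_STAGES,
                            sim = list(),
                            de = list(alpha = 0.05, min_abs_log2fc = 1),
                            novel = list(n_candidates = 4L, n_decoys = 4L,
                                         n_shuffles = 49L),
                            targets = list(n_transcripts = 40L,
                                           utr_length = 300L),
                            qpcr = list(n_targets = 6L, replicates = 3L,
                                        ct_sd = 0.15),
                            log_level = "info") {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), stages = stages, sim = sim,
                 de = de, novel = novel, targets = targets, qpcr = qpcr,
                 log_level = log_level),
            class = "smrna_pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()] object.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns the path invisibly;
#'   `read_pipeline_config` returns the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "smrna_pipeline_config"))
  x <- unclass(config)
  if (is.data.frame(x$sim$planted_effects))
    x$sim$planted_effects <- lapply(seq_len(nrow(x$sim$planted_effects)),
                                    function(i)
                                      as.list(x$sim$planted_effects[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$sim$planted_effects))
    x$sim$planted_effects <- do.call(rbind,
      lapply(x$sim$planted_effects, as.data.frame))
  do.call(pipeline_config, x)
}

log_msg <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[smrnade] ", ...)
}

#' Run the pipeline on a synthetic study
#'
#' Executes the configured stages in order and writes every stage's tables
#' under `out_dir`. The synthetic generator defines the inputs; the
#' resolved configuration is logged and written alongside the outputs so a
#' run is reproducible from its output directory alone.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (`study`,
#'   `preprocess`, `annotate`, `de`, `novel`, `targets`, `qpcr`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "smrna_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  state <- list()
  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' requires the '", what,
           "' stage, which was skipped")
  }
  scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))

  if ("simulate" %in% config$stages) {
    log_msg(config, "simulate: ", scfg$n_libraries, " libraries x ~",
            scfg$reads_per_library, " reads")
    state$study <- generate_study(scfg)
    write_references(state$study$references, file.path(out_dir, "references"))
    for (lib in state$study$libraries)
      write_library(lib, file.path(out_dir, "reads"))
  }

  if ("preprocess" %in% config$stages) {
    need("study", "preprocess")
    log_msg(config, "preprocess: filtering and collapsing")
    state$preprocess <- lapply(state$study$libraries, function(lib)
      filter_and_trim(lib$reads, scfg$adapter_3p, scfg$adapter_5p))
    for (id in names(state$preprocess))
      write_preprocess(state$preprocess[[id]], file.path(out_dir, "preprocess"),
                       prefix = id)
  }

  if ("annotate" %in% config$stages) {
    need("preprocess", "annotate")
    refs <- state$study$references
    log_msg(config, "annotate: classifying tags")
    state$annotate <- lapply(names(state$preprocess), function(id) {
      tags <- state$preprocess[[id]]$tags
      cls <- classify_tags(tags, refs$classes, refs$mature)
      mp <- map_exact(tags, refs$genome)
      comp <- class_composition(tags, cls)
      write_tsv(cbind(tags, class = cls),
                file.path(out_dir, "preprocess", paste0(id, "_classes.tsv")))
      list(library_id = id, classes = cls, composition = comp,
           mapped_percent = mp$percent)
    })
    names(state$annotate) <- names(state$preprocess)
    comp <- do.call(rbind, lapply(state$annotate, function(a)
      cbind(library = a$library_id, a$composition)))
    write_tsv(comp, file.path(out_dir, "class_composition.tsv"))
  }

  if ("de" %in% config$stages) {
    need("preprocess", "de")
    refs <- state$study$references
    log_msg(config, "de: exact test per treatment vs control")
    counts <- Reduce(function(a, b) merge(a, b, by = "mirna_id"),
                     lapply(names(state$preprocess), function(id) {
                       df <- mirna_counts(state$preprocess[[id]]$tags,
                                          refs$mature)
                       names(df)[2] <- id
                       df
                     }))
    totals <- vapply(state$preprocess, function(p)
      sum(p$tags$count), numeric(1))
    params <- de_params(alpha = config$de$alpha,
                        min_abs_log2fc = config$de$min_abs_log2fc)
    control <- scfg$library_ids[1]
    state$de <- lapply(scfg$library_ids[-1], function(tr) {
      de <- de_table(counts, control, tr, totals, params)
      write_tsv(de, file.path(out_dir, paste0("de_", tr, "_vs_",
                                              control, ".tsv")))
      write_tsv(volcano_table(de),
                file.path(out_dir, paste0("volcano_", tr, ".tsv")))
      de
    })
    names(state$de) <- scfg$library_ids[-1]
    state$de_counts <- counts
  }

  if ("novel" %in% config$stages) {
    need("study", "novel")
    refs <- state$study$references
    nc <- config$novel$n_candidates
    nd <- config$novel$n_decoys
    log_msg(config, "novel: filtering ", nc + nd, " candidates")
    cand <- with_seed(config$seed + 101L, {
      real <- refs$precursor[seq_len(min(nc, length(refs$precursor)))]
      decoys <- setNames(
        vapply(seq_len(nd), function(i)
          dinucleotide_shuffle(real[[1 + (i - 1) %% length(real)]]),
          character(1)),
        sprintf("decoy-%02d", seq_len(nd)))
      seqs <- c(real, decoys)
      scores <- setNames(c(stats::runif(length(real), 1.5, 6),
                           stats::runif(nd, 1.5, 6)), names(seqs))
      filter_candidates(seqs, scores, n_shuffles = config$novel$n_shuffles,
                        seed = config$seed + 202L)
    })
    write_tsv(cand, file.path(out_dir, "novel_candidates.tsv"))
    state$novel <- cand
  }

  if ("targets" %in% config$stages) {
    need("study", "targets")
    refs <- state$study$references
    log_msg(config, "targets: seed-match prediction and intersection")
    state$targets <- with_seed(config$seed + 303L, {
      nt <- config$targets$n_transcripts
      utrs <- setNames(random_dna(nt, config$targets$utr_length),
                       sprintf("transcript-%03d", seq_len(nt)))
      # plant exact seed sites for a third of the miRNAs
      planted <- sample(names(refs$mature), ceiling(length(refs$mature) / 3))
      for (m in planted) {
        tx <- sample(nt, sample(1:3, 1))
        site <- revcomp(substr(refs$mature[[m]], 2, 8))
        for (t in tx) {
          pos <- sample(nchar(utrs[t]) - 7, 1)
          substr(utrs[t], pos, pos + 6) <- site
        }
      }
      full <- seed_match_predict(refs$mature, utrs)
      drop_some <- function(df, frac) {
        keep <- stats::runif(nrow(df)) > frac
        df[keep, , drop = FALSE]
      }
      set_a <- full
      set_b <- drop_some(full, 0.05)
      set_c <- drop_some(full, 0.05)
      vi <- venn_intersections(set_a, set_b, set_c)
      write_tsv(data.frame(region = names(vi$regions),
                           count = as.integer(vi$regions)),
                file.path(out_dir, "target_venn_regions.tsv"))
      write_tsv(vi$common, file.path(out_dir, "target_common_pairs.tsv"))
      vi
    })
  }

  if ("qpcr" %in% config$stages) {
    need("de", "qpcr")
    log_msg(config, "qpcr: ddCt concordance on synthetic Ct values")
    de1 <- state$de[[1]]
    k <- min(config$qpcr$n_targets, nrow(de1))
    sel <- de1[order(de1$fdr), ][seq_len(k), ]
    state$qpcr <- with_seed(config$seed + 404L, {
      reps <- config$qpcr$replicates
      sd <- config$qpcr$ct_sd
      ct <- do.call(rbind, lapply(seq_len(k), function(i) {
        # treatment target Ct shifts by -log2fc cycles relative to control
        base_ct <- stats::runif(1, 20, 30)
        data.frame(
          target_id = rep(sel$mirna_id[i], 2 * reps),
          condition = rep(c("control", "treatment"), each = reps),
          replicate = rep(seq_len(reps), 2),
          ct_target = c(stats::rnorm(reps, base_ct, sd),
                        stats::rnorm(reps, base_ct - sel$log2fc[i], sd)),
          ct_reference = stats::rnorm(2 * reps, 18, sd),
          stringsAsFactors = FALSE)
      }))
      folds <- ddct_fold(ct)
      conc <- concordance(folds, de1)
      write_tsv(folds, file.path(out_dir, "qpcr_folds.tsv"))
      write_tsv(conc$per_target, file.path(out_dir, "qpcr_concordance.tsv"))
      list(ct = ct, folds = folds, concordance = conc)
    })
  }

  log_msg(config, "done: ", out_dir)
  invisible(state)
}
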