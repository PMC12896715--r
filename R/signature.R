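#' Consensus filter over independent study gene lists
#'
#' Retains genes reported by at least `min_studies` distinct studies,
#' mirroring the construction of a consensus EMT gene list from multiple
#' independent surveys.
#'
#' @param study_lists list of character vectors (one gene set per study).
#' @param min_studies minimum number of studies a gene must appear in.
#' @return A `consensus_genes` object: list with `genes` (sorted retained
#'   symbols), `support` (named integer vector over all observed genes)
#'   and `n_studies`.
#' @examples
#' consensus_filter(list(c("VIM", "CDH1"), c("VIM", "ZEB1")), 2)$genes
#' @export
consensus_filter <- function(study_lists, min_studies = 2L) {
  stopifnot(is.list(study_lists), length(study_lists) >= 1L,
            min_studies >= 1)
  study_lists <- lapply(study_lists, function(s) unique(as.character(s)))
  if (min_studies > length(study_lists))
    warning("min_studies exceeds the number of study lists: result is necessarily empty",
            call. = FALSE)
  all_genes <- sort(unique(unlist(study_lists)))
  support <- setNames(integer(length(all_genes)), all_genes)
  for (s in study_lists) support[s] <- support[s] + 1L
  structure(list(genes = names(support)[support >= min_studies],
                 support = support,
                 n_studies = length(study_lists)),
            class = "consensus_genes")
}

#' @export
print.consensus_genes <- function(x, ...) {
  cat(sprintf("consensus gene list: %d of %d genes retained (%d studies)\n",
              length(x$genes), length(x$support), x$n_studies))
  invisible(x)
}

#' Direction-concordance intersection of diagnostic and prognostic calls
#'
#' For every gene present in both the diagnostic (tumour-vs-normal) and
#' the prognostic (three-endpoint survival) tables, classifies the
#' overlap: `up_worse` (up-regulated in tumour, high expression worse) and
#' `down_better` (down-regulated, high expression better) are concordant
#' and constitute the signature; discordant combinations are retained with
#' `concordant = FALSE` for audit rather than silently dropped.  Matching
#' is by exact printed gene symbol.
#'
#' @param diagnostic data frame as from [read_diagnostic_table()] or the
#'   significant subset of [differential_expression()] (columns `gene`,
#'   `direction` with levels up/down).
#' @param prognostic data frame as from [read_prognostic_table()] or built
#'   from coherent [classify_prognosis()] calls (columns `gene`,
#'   `direction` with levels worse/better).
#' @return A data frame sorted by class (`up_worse`, `down_better`,
#'   `discordant`) then gene: columns `gene`, `diagnostic_direction`,
#'   `prognostic_direction`, `class`, `concordant`.
#' @examples
#' sig <- derive_signature(read_diagnostic_table(emt_fixture("table1")),
#'                         read_prognostic_table(emt_fixture("table2")))
#' table(sig$class)
#' @export
derive_signature <- function(diagnostic, prognostic) {
  stopifnot(is.data.frame(diagnostic), is.data.frame(prognostic),
            all(c("gene", "direction") %in% names(diagnostic)),
            all(c("gene", "direction") %in% names(prognostic)))
  if (anyDuplicated(diagnostic$gene) || anyDuplicated(prognostic$gene))
    stop("duplicate gene symbols within an input table", call. = FALSE)
  common <- intersect(diagnostic$gene, prognostic$gene)
  dd <- as.character(diagnostic$direction[match(common, diagnostic$gene)])
  pd <- as.character(prognostic$direction[match(common, prognostic$gene)])
  cls <- ifelse(dd == "up" & pd == "worse", "up_worse",
         ifelse(dd == "down" & pd == "better", "down_better", "discordant"))
  out <- data.frame(gene = common,
                    diagnostic_direction = factor(dd, levels = c("up", "down")),
                    prognostic_direction = factor(pd, levels = c("worse", "better")),
                    class = factor(cls, levels = c("up_worse", "down_better",
                                                   "discordant")),
                    concordant = cls != "discordant",
                    stringsAsFactors = FALSE)
  out <- out[order(out$class, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full signature-derivation pipeline
#'
#' Chains the four stages on user-supplied (typically simulated) inputs:
#' consensus filter over the study lists; Welch differential screen
#' restricted to consensus genes present in the expression cohort;
#' three-endpoint optimal-cutpoint prognostic classification of every
#' consensus gene present in the survival cohorts; and the
#' direction-concordance intersection of the significant diagnostic and
#' coherent prognostic calls.  Deterministic given `config$rng_seed`
#' (which seeds the permutation adjustment).
#'
#' @param study_lists list of per-study gene sets (see
#'   [simulate_study_lists()]).
#' @param expression_cohort an [expression_cohort()] object.
#' @param survival_cohorts list of three [survival_cohort()] objects
#'   covering DMFS, OS and RFS.
#' @param config an [analysis_config()] record.
#' @param out_dir optional directory: when given, every intermediate
#'   table is written there as TSV.
#' @return An `emt_pipeline` object: list with `consensus`
#'   (`consensus_genes`), `differential` (full DE table), `prognostic`
#'   (per-gene calls, one row each), `signature` (the
#'   [derive_signature()] output on the significant/coherent subsets) and
#'   `config`.
#' @export
run_full_pipeline <- function(study_lists, expression_cohort,
                              survival_cohorts, config = analysis_config(),
                              out_dir = NULL) {
  stopifnot(inherits(expression_cohort, "expr_cohort"),
            inherits(config, "emtsig_config"))
  set.seed(config$rng_seed)
  consensus <- consensus_filter(study_lists, config$min_studies)

  de_genes <- intersect(consensus$genes, rownames(expression_cohort$values))
  if (length(de_genes) == 0L) {
    warning("no consensus gene present in the expression cohort: empty signature",
            call. = FALSE)
    empty_sig <- derive_signature(
      data.frame(gene = character(), direction = factor(levels = c("up", "down"))),
      data.frame(gene = character(), direction = factor(levels = c("worse", "better"))))
    return(structure(list(consensus = consensus, differential = NULL,
                          prognostic = NULL, signature = empty_sig,
                          config = config), class = "emt_pipeline"))
  }
  sub <- expression_cohort(
    expression_cohort$values[de_genes, , drop = FALSE],
    expression_cohort$group)
  de <- differential_expression(sub, config)

  surv_genes <- Reduce(intersect, c(list(consensus$genes),
                                    lapply(survival_cohorts,
                                           function(co) colnames(co$expression))))
  prog <- do.call(rbind, lapply(surv_genes, function(g) {
    call <- classify_prognosis(g, survival_cohorts, config)
    data.frame(gene = g,
               direction = as.character(call$direction),
               coherent = call$coherent,
               p_dmfs = call$per_endpoint$p_value[1],
               p_os = call$per_endpoint$p_value[2],
               p_rfs = call$per_endpoint$p_value[3],
               adj_p_dmfs = call$per_endpoint$adjusted_p[1],
               adj_p_os = call$per_endpoint$adjusted_p[2],
               adj_p_rfs = call$per_endpoint$adjusted_p[3],
               hr_dmfs = call$per_endpoint$hazard_ratio[1],
               hr_os = call$per_endpoint$hazard_ratio[2],
               hr_rfs = call$per_endpoint$hazard_ratio[3],
               stringsAsFactors = FALSE)
  }))

  diag_sig <- de[de$significant, c("gene", "direction")]
  prog_coh <- if (is.null(prog)) {
    data.frame(gene = character(), direction = factor(levels = c("worse", "better")))
  } else {
    pc <- prog[prog$coherent, c("gene", "direction")]
    pc$direction <- factor(pc$direction, levels = c("worse", "better"))
    pc
  }
  sig <- derive_signature(diag_sig, prog_coh)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(gene = names(consensus$support),
                           support = unname(consensus$support),
                           retained = names(consensus$support) %in% consensus$genes),
                file.path(out_dir, "consensus.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(de, file.path(out_dir, "differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(prog))
      write.table(prog, file.path(out_dir, "prognostic.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_signature_report(sig, file.path(out_dir, "signature.tsv"))
  }
  structure(list(consensus = consensus, differential = de, prognostic = prog,
                 signature = sig, config = config),
            class = "emt_pipeline")
}

#' @export
print.emt_pipeline <- function(x, ...) {
  cat("EMT signature pipeline\n")
  print(x$consensus)
  if (!is.null(x$differential))
    cat(sprintf("  differential screen: %d/%d genes significant\n",
                sum(x$differential$significant), nrow(x$differential)))
  if (!is.null(x$prognostic))
    cat(sprintf("  prognostic screen:  %d/%d genes coherent\n",
                sum(x$prognostic$coherent), nrow(x$prognostic)))
  cat(sprintf("  signature: %d concordant gene(s) (%d up/worse, %d down/better)\n",
              sum(x$signature$concordant),
              sum(x$signature$class == "up_worse"),
              sum(x$signature$class == "down_better")))
  invisible(x)
}
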