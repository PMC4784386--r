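# End-to-end orchestration: the three evidence streams, module
# selection, the consensus intersection/fusion, and the
# permutation-null early-recognition experiment.

#' Run the full consensus prioritization pipeline
#'
#' Collapses duplicate probes, computes the differential-expression
#' ranking, the machine-learning ranking (mRMR reduction, ranker
#' ensemble, classifier panel, MLrel fusion), detects co-expression
#' modules in the case and control networks, selects modules whose joint
#' overlap with the DE and ML selections is enriched
#' (`merit_ml_limma >= merit_threshold`), and intersects the three
#' streams followed by min/mean rank fusion.
#'
#' The triple intersection is short-circuited exactly: when the
#' differential-expression selection (or the ML stage) is empty, the
#' consensus is empty regardless of the remaining streams, which are
#' then skipped.
#'
#' @param expr Expression tibble.
#' @param labels Phenotype tibble.
#' @param q_cutoff Adjusted-p threshold for the DE selection.
#' @param mrmr_k Genes retained by the mRMR reduction.
#' @param rankers,classifiers Panels for the ML stage.
#' @param test_fraction Held-out fraction for the classifier panel.
#' @param beta,cut_height_pct,deep_split,min_size Network/module
#'   parameters (see [build_adjacency()], [detect_modules()]).
#' @param merit_threshold Minimum joint merit for a module to enter the
#'   consensus (default 2).
#' @param known Optional known-gene set (adds hypergeometric p's to the
#'   module report).
#' @param seed Integer seed (classifier split, CV folds).
#' @return List of class `consensus_pipeline`: `de`, `de_list`,
#'   `ml_list`, `panel`, `module_assignment` (case-network modules),
#'   `module_report`, `selected_modules`, `consensus`.
#' @export
consensus_pipeline <- function(expr, labels = expr_labels(expr),
                               q_cutoff = 0.05, mrmr_k = 200L,
                               rankers = default_rankers(),
                               classifiers = default_classifiers(),
                               test_fraction = 0.25,
                               beta = 6, cut_height_pct = 99,
                               deep_split = 3, min_size = 30L,
                               merit_threshold = 2, known = NULL,
                               seed = 1L) {
  labels <- check_labeled(expr, labels)
  expr <- collapse_duplicate_genes(expr)
  out <- list(de = NULL, de_list = NULL, ml_list = NULL, panel = NULL,
              module_assignment = NULL, module_report = NULL,
              selected_modules = integer(), consensus = empty_consensus())
  class(out) <- "consensus_pipeline"

  out$de <- fit_moderated_t(expr, labels)
  out$de_list <- suppressWarnings(de_rank_select(out$de, q_cutoff))
  if (nrow(out$de_list) == 0L) return(out)  # intersection provably empty

  mrmr <- mrmr_select(expr, k = mrmr_k, labels = labels)
  expr_sel <- expr[match(mrmr$gene_id, expr$gene_id), , drop = FALSE]
  ens <- consensus_feature_ranking(expr_sel, labels, rankers)
  out$panel <- evaluate_classifier_panel(expr_sel, labels, classifiers,
                                         test_fraction, seed)
  if (!any(out$panel$valid)) return(out)
  out$ml_list <- ml_relevance_ranking(ens, out$panel)
  if (length(intersect(out$de_list$gene_id, out$ml_list$gene_id)) == 0L)
    return(out)

  case_expr <- expr[, c(TRUE, labels$group == "case"), drop = FALSE]
  network <- build_adjacency(case_expr, beta)
  out$module_assignment <- detect_modules(network, cut_height_pct,
                                          deep_split, min_size)
  stats <- module_statistics(network, out$module_assignment, out$de)
  out$module_report <- module_report(out$module_assignment, stats,
                                     out$de_list$gene_id,
                                     out$ml_list$gene_id, known)
  sel <- out$module_report$module[
    !is.na(out$module_report$merit_ml_limma) &
      out$module_report$merit_ml_limma >= merit_threshold &
      out$module_report$n_ml_limma > 0L]
  out$selected_modules <- sel
  module_genes <- out$module_assignment$gene_id[
    out$module_assignment$module %in% sel]
  genes <- suppressWarnings(
    consensus_gene_set(out$de_list, out$ml_list, module_genes))
  if (length(genes) > 0L)
    out$consensus <- fuse_ranks(genes, out$de_list, out$ml_list)
  out
}

empty_consensus <- function() {
  out <- tibble::tibble(rank = integer(), gene_id = character(),
                        rank_de = integer(), rank_ml = integer(),
                        key_min = numeric(), key_mean = numeric())
  class(out) <- c("consensus_result", class(out))
  out
}

#' @export
print.consensus_pipeline <- function(x, ...) {
  cat(sprintf("consensus pipeline: %d DE genes, %d ML genes, %d selected module(s), %d consensus genes\n",
              if (is.null(x$de_list)) 0L else nrow(x$de_list),
              if (is.null(x$ml_list)) 0L else nrow(x$ml_list),
              length(x$selected_modules), nrow(x$consensus)))
  invisible(x)
}

#' Permutation-null distribution of the consensus BEDROC
#'
#' Re-runs the consensus pipeline under label permutations and scores
#' each run's randomized-tail evaluation ranking with BEDROC at the
#' requested fraction, giving the null distribution against which the
#' observed consensus BEDROC is judged. Permuted runs exploit the
#' pipeline's exact short-circuit: a permutation whose
#' differential-expression selection is empty has an empty consensus,
#' so its evaluation ranking is a pure random permutation of the
#' background.
#'
#' @param expr,labels Data as for [consensus_pipeline()].
#' @param known Known-gene set (the actives).
#' @param n_perm Number of label permutations (default 100).
#' @param chi Fraction for BEDROC (default 0.05).
#' @param seed Integer seed driving permutations and tail randomization.
#' @param ... Passed to [consensus_pipeline()].
#' @return Numeric vector of `n_perm` null BEDROC values.
#' @export
permutation_null_bedroc <- function(expr, labels = expr_labels(expr),
                                    known, n_perm = 100L, chi = 0.05,
                                    seed = 1L, ...) {
  labels <- check_labeled(expr, labels)
  alpha <- alpha_for_fraction(chi)
  background <- unique(expr$gene_id)
  perm_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, n_perm))
  vapply(seq_len(n_perm), function(i) {
    perm_labels <- labels
    perm_labels$group <- withr::with_seed(perm_seeds[i],
                                          sample(labels$group))
    fit <- consensus_pipeline(expr, perm_labels, seed = perm_seeds[i], ...)
    ev <- build_evaluation_ranking(fit$consensus, background, known,
                                   seed = perm_seeds[i])
    rie_bedroc(ev, alpha)$bedroc
  }, numeric(1L))
}
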