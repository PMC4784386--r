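# Ranker ensemble: univariate feature-ranking statistics, ordinal rank
# positions, and the linear rank-desirability aggregation.

#' Built-in feature rankers
#'
#' Each ranker maps a labeled expression matrix to one numeric relevance
#' score per gene (higher = more disease-relevant). The default panel:
#' `tstat_mod` (absolute moderated t), `signal_to_noise` (Golub
#' \eqn{|\mu_1-\mu_2|/(s_1+s_2)}), and `info_gain`, `chi_square`,
#' `sym_uncertainty` on the 3-state discretized expression.
#'
#' @return Named list of ranker functions `function(m, y)` where `m` is a
#'   genes x samples matrix and `y` the group vector.
#' @export
default_rankers <- function() {
  list(
    tstat_mod = function(m, y) abs(matrix_moderated_t(m, y)),
    signal_to_noise = function(m, y) {
      g1 <- m[, y == "case", drop = FALSE]
      g2 <- m[, y == "control", drop = FALSE]
      s <- apply(g1, 1L, stats::sd) + apply(g2, 1L, stats::sd)
      abs(rowMeans(g1) - rowMeans(g2)) / pmax(s, .Machine$double.eps)
    },
    info_gain = function(m, y) mi_with_label(discretize_expression(m), y),
    chi_square = function(m, y) chisq_stat_by_gene(discretize_expression(m), y),
    sym_uncertainty = function(m, y) {
      disc <- discretize_expression(m)
      mi <- mi_with_label(disc, y)
      hy <- entropy_vec(table(y))
      hx <- apply(disc, 1L, function(r) entropy_vec(table(r)))
      2 * mi / pmax(hx + hy, .Machine$double.eps)
    })
}

entropy_vec <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

chisq_stat_by_gene <- function(disc, y) {
  groups <- sort(unique(y))
  n <- ncol(disc)
  obs <- array(0, dim = c(nrow(disc), 3L, 2L))
  for (s in 1:3) for (g in 1:2)
    obs[, s, g] <- rowSums(disc[, y == groups[g], drop = FALSE] == s)
  rowm <- apply(obs, c(1L, 2L), sum)
  colm <- apply(obs, c(1L, 3L), sum)
  stat <- numeric(nrow(disc))
  for (s in 1:3) for (g in 1:2) {
    expd <- rowm[, s] * colm[, g] / n
    term <- (obs[, s, g] - expd)^2 / expd
    term[expd == 0] <- 0
    stat <- stat + term
  }
  stat
}

# moderated t on a plain matrix + group vector (internal: reused by rankers)
matrix_moderated_t <- function(m, y) {
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                           tibble::as_tibble(m))
  labels <- tibble::tibble(sample_id = colnames(m), group = y)
  fit_moderated_t(expr, labels)$t_mod
}

#' Linear rank desirability
#'
#' Maps an ordinal rank position onto `[0, 1]` so that rank 1 (best) gives
#' 1 and the worst possible rank `rank_max` gives 0:
#' `d = (rank_max - rank) / (rank_max - 1)`.
#'
#' @param rank Integer rank positions (1-based).
#' @param rank_max Worst possible rank (number of genes ranked).
#' @return Desirabilities in `[0, 1]`.
#' @export
rank_desirability <- function(rank, rank_max) {
  stopifnot(rank_max >= 2L, all(rank >= 1L & rank <= rank_max))
  (rank_max - rank) / (rank_max - 1)
}

#' Ranker-ensemble consensus with rank desirabilities
#'
#' Runs every ranker over the genes of `expr`, converts each ranker's
#' scores to ordinal rank positions (1 = best; ties broken by gene id so
#' each ranker yields a total order), maps positions to the linear
#' desirability [rank_desirability()], and averages desirabilities across
#' rankers into the ensemble score `d_rank_mean`.
#'
#' @param expr Expression tibble, typically restricted to the
#'   [mrmr_select()] genes.
#' @param labels Phenotype tibble.
#' @param rankers Named list of ranker functions (default
#'   [default_rankers()]).
#' @return A tibble with one row per gene x ranker (`gene_id`, `ranker`,
#'   `rank_position`, `d_rank`) of class `ranker_ensemble`; the per-gene
#'   means are available via [ensemble_scores()].
#' @export
consensus_feature_ranking <- function(expr, labels = expr_labels(expr),
                                      rankers = default_rankers()) {
  labels <- check_labeled(expr, labels)
  if (length(rankers) < 1L) stop("need at least one ranker")
  if (is.null(names(rankers)) || any(!nzchar(names(rankers))))
    stop("rankers must be named")
  m <- expr_matrix(expr)
  if (nrow(m) < 2L) stop("need at least two genes to rank")
  ids <- rownames(m)
  rank_max <- nrow(m)
  long <- purrr::imap(rankers, function(f, name) {
    score <- f(m, labels$group)
    if (length(score) != nrow(m) || any(!is.finite(score) & !is.infinite(score)))
      stop(sprintf("ranker '%s' did not return one finite score per gene", name))
    pos <- integer(rank_max)
    pos[order(-score, ids)] <- seq_len(rank_max)
    tibble::tibble(gene_id = ids, ranker = name, rank_position = pos,
                   d_rank = rank_desirability(pos, rank_max))
  })
  out <- dplyr::bind_rows(long)
  attr(out, "rank_max") <- rank_max
  class(out) <- c("ranker_ensemble", class(out))
  out
}

#' Per-gene ensemble desirability scores
#'
#' @param ens A [consensus_feature_ranking()] result.
#' @return Tibble `gene_id`, `d_rank_mean` (mean desirability over rankers).
#' @export
ensemble_scores <- function(ens) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(ens), .data$gene_id),
                   d_rank_mean = mean(.data$d_rank), .groups = "drop")
}
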