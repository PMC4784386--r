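# The consensus rule (triple intersection) and min/mean rank fusion.

#' Consensus gene set: triple intersection of evidence streams
#'
#' Genes present in the differential-expression list, the
#' machine-learning list, and the union of the prioritized co-expression
#' modules.
#'
#' @param de_list,ml_list Ranked-list tibbles (or character vectors).
#' @param module_genes Character vector: union of the genes in the
#'   selected modules.
#' @return Character vector of consensus genes (unordered); empty with a
#'   warning when the intersection is empty.
#' @export
consensus_gene_set <- function(de_list, ml_list, module_genes) {
  de <- ranked_genes(de_list)
  ml <- ranked_genes(ml_list)
  out <- intersect(intersect(de, ml), module_genes)
  if (length(out) == 0L) warning("consensus intersection is empty")
  out
}

ranked_genes <- function(x) {
  if (is.character(x)) x else x$gene_id
}

#' Min/mean rank fusion of the consensus genes
#'
#' Orders the consensus genes by ascending minimum of their
#' differential-expression and machine-learning ranks, breaking ties by
#' the ascending mean of the two ranks and finally by gene id. The result
#' depends only on rank positions, so it is invariant to any monotone
#' re-scoring of either source list.
#'
#' @param genes Character vector of consensus genes.
#' @param de_list,ml_list Ranked-list tibbles covering every gene.
#' @return Tibble of class `consensus_result`: `rank`, `gene_id`,
#'   `rank_de`, `rank_ml`, `key_min`, `key_mean`.
#' @export
fuse_ranks <- function(genes, de_list, ml_list) {
  rank_de <- de_list$rank[match(genes, de_list$gene_id)]
  rank_ml <- ml_list$rank[match(genes, ml_list$gene_id)]
  if (anyNA(rank_de) || anyNA(rank_ml))
    stop("gene(s) missing from a source ranking: ",
         paste(utils::head(genes[is.na(rank_de) | is.na(rank_ml)], 5L),
               collapse = ", "))
  key_min <- pmin(rank_de, rank_ml)
  key_mean <- (rank_de + rank_ml) / 2
  ord <- order(key_min, key_mean, genes)
  out <- tibble::tibble(
    rank = seq_along(genes), gene_id = genes[ord],
    rank_de = rank_de[ord], rank_ml = rank_ml[ord],
    key_min = key_min[ord], key_mean = key_mean[ord])
  class(out) <- c("consensus_result", class(out))
  out
}
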