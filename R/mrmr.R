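# Mutual-information machinery shared by the mRMR selector and the
# discretization-based feature rankers.

# Per-gene 3-state discretization: z-score within gene, states split at
# +/- 0.5 SD (the canonical mRMR configuration for expression data).
# Returns an integer matrix (genes x samples) with values 1/2/3.
discretize_expression <- function(m, threshold = 0.5) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  sd[sd == 0] <- 1  # constant genes -> all state 2
  z <- (m - mu) / sd
  d <- matrix(2L, nrow(m), ncol(m), dimnames = dimnames(m))
  d[z < -threshold] <- 1L
  d[z > threshold] <- 3L
  d
}

# Plug-in mutual information (nats) from a contingency table of counts.
mi_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)][nz] * py[col(p)][nz])))
}

# MI of every row of a discretized matrix with a 2-level label, vectorized
# over genes.
mi_with_label <- function(disc, y) {
  stopifnot(length(unique(y)) == 2L)
  groups <- sort(unique(y))
  counts <- array(0, dim = c(nrow(disc), 3L, 2L))
  for (s in 1:3) for (g in 1:2)
    counts[, s, g] <- rowSums(disc[, y == groups[g], drop = FALSE] == s)
  n <- ncol(disc)
  p <- counts / n
  px <- apply(p, c(1L, 2L), sum)   # genes x 3
  py <- apply(p, c(1L, 3L), sum)   # genes x 2
  mi <- numeric(nrow(disc))
  for (s in 1:3) for (g in 1:2) {
    term <- p[, s, g] * log(p[, s, g] / (px[, s] * py[, g]))
    term[p[, s, g] == 0] <- 0
    mi <- mi + term
  }
  mi
}

# MI of one discretized gene against every row of disc (vectorized; used
# for the incremental redundancy term of greedy mRMR).
mi_with_gene <- function(disc, target_states) {
  n <- ncol(disc)
  mi <- numeric(nrow(disc))
  counts <- vector("list", 3L)
  for (s2 in 1:3) {
    sel <- target_states == s2
    counts[[s2]] <- vapply(1:3, function(s1)
      rowSums(disc[, sel, drop = FALSE] == s1), numeric(nrow(disc)))
  }
  p <- lapply(counts, function(cc) cc / n)        # list over s2 of genes x s1
  px <- p[[1L]] + p[[2L]] + p[[3L]]               # genes x 3 (marginal of rows)
  py <- vapply(p, rowSums, numeric(nrow(disc)))   # genes x 3 (marginal of target)
  for (s2 in 1:3) for (s1 in 1:3) {
    term <- p[[s2]][, s1] * log(p[[s2]][, s1] / (px[, s1] * py[, s2]))
    term[p[[s2]][, s1] == 0] <- 0
    mi <- mi + term
  }
  mi
}

#' Greedy minimum-redundancy maximum-relevance gene selection
#'
#' Selects `k` genes by the greedy mRMR rule with the mutual-information
#' difference (MID) objective on 3-state discretized expression: the first
#' gene maximizes MI with the case/control label; each subsequent gene
#' maximizes `MI(gene; label) - mean MI(gene; selected so far)`. Ties are
#' broken by gene id for determinism.
#'
#' @param expr Expression tibble.
#' @param k Number of genes to select (default 500). When `k` exceeds the
#'   gene count all genes are returned with a warning.
#' @param labels Phenotype tibble.
#' @param threshold Discretization half-width in SD units (default 0.5).
#' @return Ranked-list tibble in selection order; `score` is the greedy
#'   objective value at selection time.
#' @export
mrmr_select <- function(expr, k = 500L, labels = expr_labels(expr),
                        threshold = 0.5) {
  labels <- check_labeled(expr, labels)
  if (k < 1L) stop("k must be >= 1")
  m <- expr_matrix(expr)
  if (anyDuplicated(rownames(m))) stop("gene ids must be unique (collapse first)")
  n_genes <- nrow(m)
  if (k > n_genes) {
    warning(sprintf("k = %d exceeds gene count %d; returning all genes", k, n_genes))
    k <- n_genes
  }
  disc <- discretize_expression(m, threshold)
  relevance <- mi_with_label(disc, labels$group)

  selected <- integer(k)
  redundancy_sum <- numeric(n_genes)
  available <- rep(TRUE, n_genes)
  ids <- rownames(m)
  score <- numeric(k)
  for (t in seq_len(k)) {
    obj <- if (t == 1L) relevance else relevance - redundancy_sum / (t - 1L)
    obj[!available] <- -Inf
    # snap to 10 decimals so numerically tied objectives resolve by id
    best <- order(-round(obj, 10L), ids)[1L]
    selected[t] <- best
    score[t] <- obj[best]
    available[best] <- FALSE
    if (t < k)
      redundancy_sum <- redundancy_sum + mi_with_gene(disc, disc[best, ])
  }
  new_ranked_list(ids[selected], score)
}
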