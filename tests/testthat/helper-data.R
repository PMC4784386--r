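# Shared fixture builders (everything generated in code; no data files).

# expression tibble from a plain matrix, with optional attached labels
make_expr <- function(m, gene_ids = NULL, sample_ids = NULL, labels = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(ncol(m)))
  colnames(m) <- sample_ids
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                           tibble::as_tibble(m))
  if (!is.null(labels)) {
    attr(expr, "labels") <- tibble::tibble(sample_id = sample_ids,
                                           group = labels)
  }
  expr
}

two_group_labels <- function(n_case, n_control) {
  rep(c("case", "control"), c(n_case, n_control))
}

# small labeled dataset with one clearly informative gene
informative_fixture <- function(n_genes = 20, n_per_group = 10, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    m <- matrix(stats::rnorm(n_genes * n), n_genes)
    m[1, ] <- rep(c(3, -3), each = n_per_group) + stats::rnorm(n, sd = 0.1)
    make_expr(m, labels = two_group_labels(n_per_group, n_per_group))
  })
}

# reduced-scale planted dataset used across pipeline tests
small_planted <- function(seed = 1) {
  spec <- synthetic_spec(
    n_genes = 300L, n_case = 20L, n_control = 20L,
    modules = tibble::tibble(size = c(40L, 30L, 20L), loading = 2),
    n_de = 30L, de_effect = 1.5, n_known_planted = 20L,
    known_decoys = 10L)
  generate_dataset(spec, seed = seed)
}

# independent brute-force step-up FDR adjustment
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exhaustive hypergeometric upper tail from binomial coefficients
hyper_tail_brute <- function(N, K, n, m) {
  ms <- m:min(n, K)
  sum(choose(K, ms) * choose(N - K, n - ms)) / choose(N, n)
}

# plug-in mutual information of two discrete vectors via table()
mi_table <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  tot
}

# exhaustive greedy mRMR on a discretized matrix (independent of the
# package's vectorized path)
mrmr_brute <- function(disc, y, k) {
  ids <- rownames(disc)
  relevance <- apply(disc, 1L, mi_table, y = y)
  selected <- character(0)
  available <- ids
  for (t in seq_len(k)) {
    obj <- vapply(available, function(g) {
      red <- if (length(selected) == 0) 0 else
        mean(vapply(selected, function(s)
          mi_table(disc[g, ], disc[s, ]), numeric(1)))
      relevance[g] - red
    }, numeric(1))
    best <- available[order(-round(obj, 10), available)][1]
    selected <- c(selected, best)
    available <- setdiff(available, best)
  }
  selected
}

# random evaluation ranking: empty prioritized head, seeded tail
random_ranking <- function(N, n_active, seed) {
  background <- sprintf("b%05d", seq_len(N))
  actives <- sample(background, n_active)  # caller controls RNG
  build_evaluation_ranking(character(0), background, actives, seed = seed)
}
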