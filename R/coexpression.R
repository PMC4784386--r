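# Weighted gene co-expression networks: soft-threshold adjacency,
# scale-free fit, topological overlap, height-percentile module
# detection, and the module connectivity / expression / merit statistics.

#' Build an unsigned weighted co-expression adjacency
#'
#' `a_ij = |cor(i, j)|^beta` (Pearson), diagonal zeroed. The node
#' connectivity `k` is the adjacency row sum.
#'
#' @param expr Expression tibble (the samples of one group, typically).
#' @param beta Soft-threshold power (default 6, chosen by the scale-free
#'   topology criterion; inspect [scale_free_fit()]).
#' @return List of class `coexpr_network` with elements `adjacency`
#'   (symmetric genes x genes matrix in `[0,1]`), `beta` and `node_k`.
#' @export
build_adjacency <- function(expr, beta = 6) {
  if (beta < 1) stop("beta must be >= 1")
  m <- expr_matrix(expr)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(m)[sds == 0], 5L), collapse = ", "))
  a <- abs(stats::cor(t(m)))^beta
  diag(a) <- 0
  new_coexpr_network(a, beta)
}

new_coexpr_network <- function(adjacency, beta) {
  structure(list(adjacency = adjacency, beta = beta,
                 node_k = rowSums(adjacency)),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpression network: %d genes, beta = %g, mean k = %.3f\n",
              nrow(x$adjacency), x$beta, mean(x$node_k)))
  invisible(x)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the node connectivities into `n_bins` equal-width bins and returns
#' the R-squared of the regression of `log10(bin frequency)` on
#' `log10(mean bin connectivity)` -- the scale-free criterion used to pick
#' the soft-threshold power.
#'
#' @param network A `coexpr_network`, or a numeric vector of
#'   connectivities.
#' @param n_bins Number of bins (default 10).
#' @return The fit R-squared, with the regression slope in attribute
#'   `"slope"`.
#' @export
scale_free_fit <- function(network, n_bins = 10L) {
  k <- if (inherits(network, "coexpr_network")) network$node_k else network
  if (diff(range(k)) == 0)
    stop("all connectivities equal: degenerate binning")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 2L) stop("fewer than 2 occupied bins")
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  r2 <- summary(fit)$r.squared
  attr(r2, "slope") <- unname(stats::coef(fit)[2L])
  r2
}

#' Topological overlap matrix
#'
#' Unsigned TOM: `(L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L = A %*% A`; diagonal set to 1.
#'
#' @param network A `coexpr_network`.
#' @return Symmetric matrix in `[0, 1]`.
#' @export
topological_overlap <- function(network) {
  a <- network$adjacency
  k <- network$node_k
  l <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by height-percentile tree cutting
#'
#' Average-linkage hierarchical clustering on `1 - TOM` (or `1 -
#' adjacency` with `dissimilarity = "adjacency"`), cut at a percentile of
#' the dendrogram merge heights. `deep_split` (0-4) lowers the effective
#' cutting percentile by 5 points per unit, producing progressively finer
#' partitions. A branch only becomes a module when it is cleanly
#' separated from its surroundings: the height at which it joins the rest
#' of the tree must exceed its own topmost internal merge by at least
#' `min_gap` times the dendrogram height range (incoherent "comb"
#' branches of unrelated genes fail this and stay unassigned). Branches
#' smaller than `min_size` are left unassigned (module 0). Module labels
#' are ordered by decreasing size.
#'
#' @param network A `coexpr_network`.
#' @param cut_height_pct Percentile (0-100) of merge heights for the
#'   primary cut (default 99).
#' @param deep_split Split sensitivity 0-4 (default 3).
#' @param min_size Minimum module size (default 30).
#' @param min_gap Minimum branch separation, as a fraction of the
#'   dendrogram height range (default 0.025).
#' @param dissimilarity `"tom"` (default) or `"adjacency"`.
#' @return Tibble `gene_id`, `module` (integer; 0 = unassigned) of class
#'   `module_set`, with the `hclust` tree in attribute `"tree"`.
#' @export
detect_modules <- function(network, cut_height_pct = 99, deep_split = 3,
                           min_size = 30L, min_gap = 0.025,
                           dissimilarity = c("tom", "adjacency")) {
  dissimilarity <- match.arg(dissimilarity)
  n_genes <- nrow(network$adjacency)
  if (min_size > n_genes) stop("min_size exceeds gene count")
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4")
  diss <- if (dissimilarity == "tom") 1 - topological_overlap(network)
          else 1 - network$adjacency
  diag(diss) <- 0
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  pct_eff <- max(0, cut_height_pct - 5 * deep_split) / 100
  h_cut <- stats::quantile(hc$height, pct_eff, names = FALSE)
  gap_min <- min_gap * diff(range(c(0, hc$height)))
  labels <- select_branches(hc, h_cut, gap_min, min_size)
  labels <- relabel_by_size(labels)
  out <- tibble::tibble(gene_id = rownames(network$adjacency),
                        module = labels)
  attr(out, "tree") <- hc
  class(out) <- c("module_set", class(out))
  out
}

# Modules = maximal dendrogram nodes that (a) complete below the cut
# height, (b) reach min_size, and (c) are separated from the merge that
# absorbs them by at least gap_min (the root counts as infinitely
# separated). Chained "comb" branches of unrelated genes fail (c):
# each of their merges sits immediately below the next.
select_branches <- function(hc, h_cut, gap_min, min_size) {
  n_merge <- nrow(hc$merge)
  n <- n_merge + 1L
  size <- integer(n_merge)
  members <- vector("list", n_merge)
  parent_h <- rep(Inf, n_merge)
  for (i in seq_len(n_merge)) {
    ch <- hc$merge[i, ]
    members[[i]] <- c(
      if (ch[1L] < 0) -ch[1L] else members[[ch[1L]]],
      if (ch[2L] < 0) -ch[2L] else members[[ch[2L]]])
    size[i] <- length(members[[i]])
    for (c in ch[ch > 0]) parent_h[c] <- hc$height[i]
  }
  qualify <- size >= min_size & hc$height <= h_cut + 1e-12 &
    (parent_h - hc$height) >= gap_min
  selected <- logical(n_merge)
  under_selected <- logical(n_merge)
  for (i in rev(seq_len(n_merge))) {  # heights non-increasing downwards
    selected[i] <- qualify[i] && !under_selected[i]
    for (c in hc$merge[i, ][hc$merge[i, ] > 0])
      under_selected[c] <- under_selected[i] || selected[i]
  }
  labels <- integer(n)
  for (i in which(selected)) labels[members[[i]]] <- i
  labels
}

# assigned modules renumbered 1..M by decreasing size; 0 stays 0
relabel_by_size <- function(labels) {
  assigned <- labels[labels != 0L]
  if (length(assigned) == 0L) return(as.integer(labels))
  sizes <- sort(table(assigned), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  out <- labels
  out[labels != 0L] <- map[as.character(assigned)]
  as.integer(out)
}

#' Per-module connectivity and differential-expression statistics
#'
#' For every module: size `n`, mean whole-network connectivity `mean_k`
#' (adjacency row sums over all genes), mean intramodular connectivity
#' `mean_k_intra` (row sums restricted to the module, hence
#' `mean_k_intra <= mean_k`), and the mean case-minus-control log
#' expression difference `mean_log_diff` from a differential-expression
#' result.
#'
#' @param network The `coexpr_network` the modules were detected in.
#' @param modules A [detect_modules()] tibble (or any tibble with
#'   `gene_id`, `module`).
#' @param de A [fit_moderated_t()] result on the same gene universe
#'   (optional; `mean_log_diff` is `NA` without it).
#' @return Tibble with one row per module (module 0 excluded).
#' @export
module_statistics <- function(network, modules, de = NULL) {
  a <- network$adjacency
  missing <- setdiff(modules$gene_id, rownames(a))
  if (length(missing) > 0L)
    stop("module gene(s) absent from the network: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  k_all <- network$node_k
  mods <- sort(unique(modules$module[modules$module != 0L]))
  rows <- lapply(mods, function(mod) {
    genes <- modules$gene_id[modules$module == mod]
    idx <- match(genes, rownames(a))
    k_intra <- rowSums(a[idx, idx, drop = FALSE])
    mean_log_diff <- if (is.null(de)) NA_real_ else
      mean(de$log_diff[match(genes, de$gene_id)])
    tibble::tibble(module = mod, n = length(genes),
                   mean_k = mean(k_all[idx]),
                   mean_k_intra = mean(k_intra),
                   mean_log_diff = mean_log_diff)
  })
  dplyr::bind_rows(rows)
}

#' Module merit: fold-enrichment in genes from another prioritization
#'
#' `(n_in_module / selected_total) / (module_size / background_size)`:
#' the fraction of the selected genes falling in the module relative to
#' the module's share of the background. Merit > 1 means the module is
#' enriched in selected genes.
#'
#' @param n_in_module Selected genes inside the module.
#' @param selected_total Total selected genes.
#' @param module_size Genes in the module.
#' @param background_size Genes in the background.
#' @return The merit ratio.
#' @export
module_merit <- function(n_in_module, selected_total, module_size,
                         background_size) {
  if (any(selected_total == 0) || any(module_size == 0) ||
      any(background_size == 0))
    stop("selected_total, module_size and background_size must be nonzero")
  if (any(n_in_module > pmin(selected_total, module_size)))
    stop("n_in_module cannot exceed selected_total or module_size")
  if (any(background_size < module_size))
    stop("background_size must be >= module_size")
  (n_in_module / selected_total) / (module_size / background_size)
}

#' Module prioritization report
#'
#' Ranks modules for consensus selection: per module, the overlap counts
#' and merits against the differential-expression list, the
#' machine-learning list and their intersection, plus a hypergeometric
#' upper-tail p against an optional known-gene set. Modules are ordered by
#' decreasing joint merit.
#'
#' @param modules [detect_modules()] tibble.
#' @param stats [module_statistics()] tibble for the same modules.
#' @param de_genes Character vector: differential-expression selection.
#' @param ml_genes Character vector: machine-learning selection.
#' @param known Optional character vector of known disease genes.
#' @return Tibble with one row per module, class `module_report`.
#' @export
module_report <- function(modules, stats, de_genes, ml_genes, known = NULL) {
  background_n <- nrow(modules)
  both <- intersect(de_genes, ml_genes)
  rows <- lapply(stats$module, function(mod) {
    genes <- modules$gene_id[modules$module == mod]
    n <- length(genes)
    n_de <- length(intersect(genes, de_genes))
    n_ml <- length(intersect(genes, ml_genes))
    n_both <- length(intersect(genes, both))
    tibble::tibble(
      module = mod, n = n,
      n_limma = n_de,
      merit_limma = if (length(de_genes)) module_merit(n_de, length(de_genes), n, background_n) else NA_real_,
      n_ml = n_ml,
      merit_ml = if (length(ml_genes)) module_merit(n_ml, length(ml_genes), n, background_n) else NA_real_,
      n_ml_limma = n_both,
      merit_ml_limma = if (length(both)) module_merit(n_both, length(both), n, background_n) else NA_real_,
      hypergeom_p = if (is.null(known)) NA_real_ else
        hypergeom_upper_tail(background_n,
                             length(intersect(known, modules$gene_id)),
                             n, length(intersect(genes, known))))
  })
  out <- dplyr::left_join(dplyr::bind_rows(rows), stats, by = c("module", "n"))
  out <- out[order(-replace(out$merit_ml_limma, is.na(out$merit_ml_limma), -Inf),
                   out$module), , drop = FALSE]
  class(out) <- c("module_report", class(out))
  out
}

#' Connectivity overview plot for a module report
#'
#' @param object A [module_report()] tibble.
#' @param ... Unused.
#' @return A ggplot: mean intramodular vs whole-network connectivity,
#'   point size = module size, colour = mean log expression difference.
#' @method autoplot module_report
#' @export
autoplot.module_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mean_k, y = .data$mean_k_intra,
                               size = .data$n,
                               colour = .data$mean_log_diff)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey85",
                                    high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "mean whole-network connectivity",
                  y = "mean intramodular connectivity",
                  size = "module size", colour = "mean log diff") +
    ggplot2::theme_minimal()
}
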