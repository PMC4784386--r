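# Synthetic case/control expression datasets with planted differential
# expression, planted co-expression modules (single latent factor per
# module) and a flagged known-gene set containing decoys.

#' Specification for a synthetic expression dataset
#'
#' The defaults emulate, at reduced scale, a two-group brain expression
#' study: 2,000 genes by 30 case + 30 control samples, three co-expressed
#' modules driven by one latent factor each, 60 differentially expressed
#' genes (1 SD shift in cases) placed inside the modules so that modules
#' are coherently up- or down-regulated, and a flagged "known disease
#' gene" set of 40 planted genes plus 35 decoys -- roughly the ~3.8%
#' known-gene background fraction of real disease-gene panels.
#'
#' @param n_genes,n_case,n_control Dimensions.
#' @param modules Tibble/data frame with columns `size` and `loading`
#'   (latent-factor loading); module genes occupy the first
#'   `sum(size)` gene indices. The intra-module correlation is
#'   `loading^2 / (loading^2 + noise_sd^2)`; the default loading of 2
#'   over unit noise gives correlation 0.8, a tight, clearly resolvable
#'   co-expression module.
#' @param n_de Number of differentially expressed genes.
#' @param de_effect Case-minus-control shift in marginal SD units.
#' @param de_in_modules Place the DE genes inside the planted modules
#'   (split evenly; default `TRUE`) rather than among unstructured genes.
#' @param n_known_planted DE genes flagged as "known".
#' @param known_decoys Non-DE genes flagged as "known" (decoys make TP
#'   rate and fold-enrichment non-trivial).
#' @param noise_sd Independent noise SD.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_case = 30L, n_control = 30L,
                           modules = tibble::tibble(size = c(100L, 80L, 60L),
                                                    loading = 2.0),
                           n_de = 60L, de_effect = 1.0,
                           de_in_modules = TRUE,
                           n_known_planted = 40L, known_decoys = 35L,
                           noise_sd = 1.0) {
  modules <- tibble::as_tibble(modules)
  stopifnot(all(c("size", "loading") %in% names(modules)))
  if (sum(modules$size) > n_genes) stop("module sizes exceed gene count")
  if (n_de > n_genes) stop("n_de exceeds gene count")
  if (de_in_modules && n_de > sum(modules$size))
    stop("n_de exceeds total module size with de_in_modules = TRUE")
  if (n_known_planted > n_de) stop("n_known_planted exceeds n_de")
  if (any(!is.finite(de_effect)) || !is.finite(noise_sd) || noise_sd <= 0)
    stop("effect sizes and noise_sd must be finite (noise_sd > 0)")
  structure(list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
                 n_control = as.integer(n_control), modules = modules,
                 n_de = as.integer(n_de), de_effect = de_effect,
                 de_in_modules = de_in_modules,
                 n_known_planted = as.integer(n_known_planted),
                 known_decoys = as.integer(known_decoys),
                 noise_sd = noise_sd),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled expression dataset
#'
#' Gene values are `loading x module latent factor + independent
#' Gaussian noise`; differentially expressed genes additionally receive a
#' `de_effect x marginal-SD` mean shift in the case samples. The flagged
#' known-gene set is the first `n_known_planted` DE genes plus
#' `known_decoys` genes sampled from the non-DE remainder. Output is
#' bit-identical for a given seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List: `expr` (expression tibble with labels attached),
#'   `labels`, `known` (character vector), `truth` (tibble `gene_id`,
#'   `module`, `de`, `known` recording the planted structure).
#' @export
generate_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(seed, {
    n_samples <- spec$n_case + spec$n_control
    gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
    sample_ids <- c(sprintf("case_%02d", seq_len(spec$n_case)),
                    sprintf("ctrl_%02d", seq_len(spec$n_control)))
    group <- rep(c("case", "control"), c(spec$n_case, spec$n_control))

    m <- matrix(stats::rnorm(spec$n_genes * n_samples, sd = spec$noise_sd),
                nrow = spec$n_genes,
                dimnames = list(gene_ids, sample_ids))
    module_of <- integer(spec$n_genes)
    offset <- 0L
    for (j in seq_len(nrow(spec$modules))) {
      size <- spec$modules$size[j]
      idx <- offset + seq_len(size)
      factor_j <- stats::rnorm(n_samples)
      m[idx, ] <- m[idx, ] +
        spec$modules$loading[j] * matrix(factor_j, size, n_samples,
                                         byrow = TRUE)
      module_of[idx] <- j
      offset <- offset + size
    }

    de_idx <- if (spec$de_in_modules) {
      per_mod <- distribute_evenly(spec$n_de, nrow(spec$modules))
      unlist(lapply(seq_len(nrow(spec$modules)), function(j) {
        which(module_of == j)[seq_len(per_mod[j])]
      }), use.names = FALSE)
    } else {
      seq_len(spec$n_de)
    }
    marginal_sd <- ifelse(module_of > 0L,
                          sqrt(spec$modules$loading[pmax(module_of, 1L)]^2 +
                                 spec$noise_sd^2),
                          spec$noise_sd)
    m[de_idx, group == "case"] <- m[de_idx, group == "case"] +
      spec$de_effect * marginal_sd[de_idx]

    known_planted <- gene_ids[de_idx[seq_len(spec$n_known_planted)]]
    decoy_pool <- setdiff(seq_len(spec$n_genes), de_idx)
    decoys <- gene_ids[sample(decoy_pool, spec$known_decoys)]
    known <- c(known_planted, decoys)

    labels <- tibble::tibble(sample_id = sample_ids, group = group)
    expr <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                             tibble::as_tibble(m))
    attr(expr, "labels") <- labels
    truth <- tibble::tibble(
      gene_id = gene_ids, module = module_of,
      de = seq_len(spec$n_genes) %in% de_idx,
      known = gene_ids %in% known)
    list(expr = expr, labels = labels, known = known, truth = truth)
  })
}

distribute_evenly <- function(total, bins) {
  base <- total %/% bins
  extra <- total %% bins
  base + (seq_len(bins) <= extra)
}
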