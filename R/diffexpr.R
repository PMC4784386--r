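#' Moderated-t differential expression between case and control samples
#'
#' Fits a gene-wise two-group model and computes an empirical-Bayes
#' moderated t statistic: gene-wise residual variances are shrunk towards a
#' pooled prior estimated from all genes by method of moments on the log
#' sample variances, and p-values are drawn from a t reference with
#' augmented degrees of freedom (residual + prior). The sign convention is
#' case minus control.
#'
#' With prior degrees of freedom `d0` and prior variance `s0^2`, the
#' posterior variance for a gene with residual df `d` and pooled variance
#' `s^2` is `(d0*s0^2 + d*s^2) / (d0 + d)`; if the gene-wise variances are
#' all (numerically) equal the prior is degenerate (`d0 = Inf`) and the
#' common variance is used directly.
#'
#' @param expr Expression tibble (`gene_id` first column, one numeric
#'   column per sample).
#' @param labels Phenotype tibble (`sample_id`, `group`); defaults to the
#'   labels attached to `expr`.
#' @return A tibble with one row per gene: `gene_id`, `mean_case`,
#'   `mean_control`, `log_diff` (case - control), `t_mod`, `p`, `q`
#'   (Benjamini-Hochberg adjusted), plus the prior estimates in attributes
#'   `df_prior` and `var_prior`.
#' @export
fit_moderated_t <- function(expr, labels = expr_labels(expr)) {
  labels <- check_labeled(expr, labels)
  m <- expr_matrix(expr)
  case <- m[, labels$group == "case", drop = FALSE]
  ctrl <- m[, labels$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  mean_case <- rowMeans(case)
  mean_control <- rowMeans(ctrl)
  log_diff <- mean_case - mean_control
  d <- n1 + n2 - 2L
  ss <- rowSums((case - mean_case)^2) + rowSums((ctrl - mean_control)^2)
  s2 <- ss / d
  if (all(s2 == 0)) stop("all gene-wise variances are zero; no prior estimable")

  prior <- estimate_variance_prior(s2, d)
  if (is.finite(prior$df)) {
    s2_post <- (prior$df * prior$var + d * s2) / (prior$df + d)
    df_total <- prior$df + d
  } else {
    s2_post <- rep(prior$var, length(s2))
    df_total <- Inf
  }
  t_mod <- log_diff / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- tibble::tibble(
    gene_id = rownames(m), mean_case = unname(mean_case),
    mean_control = unname(mean_control), log_diff = unname(log_diff),
    t_mod = unname(t_mod), p = unname(p), q = unname(bh_adjust(p)))
  attr(out, "df_prior") <- prior$df
  attr(out, "var_prior") <- prior$var
  class(out) <- c("de_result", class(out))
  out
}

# Method-of-moments fit of a scaled inverse chi-square prior to the
# gene-wise sample variances, on the log scale (zero variances excluded
# from the moment equations; they still receive full shrinkage).
estimate_variance_prior <- function(s2, d) {
  z <- log(s2[s2 > 0])
  e <- z - digamma(d / 2) + log(d / 2)
  e_mean <- mean(e)
  e_var <- if (length(e) > 1L) sum((e - e_mean)^2) / (length(e) - 1L) else 0
  rhs <- e_var - trigamma(d / 2)
  if (rhs <= 0) {
    # variances (numerically) homogeneous: degenerate prior
    return(list(df = Inf, var = exp(e_mean)))
  }
  df0 <- 2 * inv_trigamma(rhs)
  var0 <- exp(e_mean + digamma(df0 / 2) - log(df0 / 2))
  list(df = df0, var = var0)
}

# Newton inversion of trigamma (monotone decreasing on (0, Inf))
inv_trigamma <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard false-discovery-rate step-up adjustment (monotone, capped at
#' 1), delegating to [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select and rank significantly differential genes
#'
#' Keeps genes with adjusted p-value below `q_cutoff`, ordered by ascending
#' raw p (ties broken by gene id); the reported score is `-log10(p)`, so
#' higher means more significant. Selections are nested in `q_cutoff`.
#'
#' @param de A [fit_moderated_t()] result.
#' @param q_cutoff Adjusted-p threshold (default 0.05).
#' @return Ranked-list tibble (`rank`, `gene_id`, `score`); empty (with a
#'   warning) when nothing passes.
#' @export
de_rank_select <- function(de, q_cutoff = 0.05) {
  hit <- de[de$q < q_cutoff, , drop = FALSE]
  if (nrow(hit) == 0L) {
    warning(sprintf("no genes with adjusted p < %g", q_cutoff))
    return(new_ranked_list(character(), numeric()))
  }
  hit <- hit[order(hit$p, hit$gene_id), , drop = FALSE]
  new_ranked_list(hit$gene_id, -log10(hit$p))
}

#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_q05 = sum(x$q < 0.05),
    n_q25 = sum(x$q < 0.25),
    df_prior = attr(x, "df_prior"),
    var_prior = attr(x, "var_prior"))
}

#' Volcano plot of a differential-expression result
#'
#' @param object A [fit_moderated_t()] result.
#' @param q_cutoff Highlighting threshold on the adjusted p-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, q_cutoff = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$q < q_cutoff
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_diff,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean(case) - mean(control) [log scale]",
                  y = expression(-log[10](p)),
                  colour = sprintf("q < %g", q_cutoff)) +
    ggplot2::theme_minimal()
}
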