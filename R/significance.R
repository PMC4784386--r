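# Statistical validation: hypergeometric upper tail, bootstrap
# resampling null with fold-enrichment, and Wilcoxon signed-rank
# comparison of rankings.

#' Hypergeometric upper-tail probability of an overlap
#'
#' Probability of drawing `m` or more flagged genes (inclusive tail) when
#' `n` genes are drawn without replacement from a background of `N` genes
#' of which `K` are flagged.
#'
#' @param N Background size.
#' @param K Flagged (known disease) genes in the background.
#' @param n Prioritized set size.
#' @param m Observed hits.
#' @return `P(X >= m)` under Hypergeometric(N, K, n).
#' @export
hypergeom_upper_tail <- function(N, K, n, m) {
  if (m > n || n > N || K > N || m < 0 || K < 0)
    stop("inconsistent counts: need 0 <= m <= n <= N and 0 <= K <= N")
  stats::phyper(m - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bootstrap resampling null for a prioritized set's enrichment
#'
#' Draws `reps` uniform gene sets of size `n` from the background,
#' counts the known-gene hits in each, and compares the observed hit
#' count against the null draws: summary statistics of the null, a
#' one-sided Wilcoxon signed-rank p-value that the null hit counts fall
#' below the observation, the fold-enrichment `observed_m / mean(null)`
#' and the TP rate `observed_m / n`.
#'
#' @param background Character vector: the gene universe.
#' @param known Character vector: known disease genes (must intersect the
#'   background).
#' @param n Prioritized set size.
#' @param observed_m Observed hits in the prioritized set.
#' @param reps Number of bootstrap draws (default 100).
#' @param seed Integer seed.
#' @return One-row tibble of class `significance_report`: `N`, `K`, `n`,
#'   `m`, `hypergeom_p`, `reps`, `seed`, `boot_mean`, `boot_median`,
#'   `boot_min`, `boot_max`, `boot_sd`, `wilcoxon_p`, `fold_enrichment`,
#'   `tp_rate`.
#' @export
bootstrap_enrichment <- function(background, known, n, observed_m,
                                 reps = 100L, seed = 1L) {
  if (reps < 2L) stop("reps must be >= 2")
  if (n > length(background)) stop("n exceeds background size")
  known_in <- intersect(known, background)
  if (length(known_in) == 0L)
    stop("known set does not intersect the background")
  K <- length(known_in)
  N <- length(background)
  is_known <- background %in% known_in
  hits <- withr::with_seed(seed, vapply(seq_len(reps), function(i)
    sum(is_known[sample.int(N, n)]), integer(1L)))
  wres <- suppressWarnings(
    stats::wilcox.test(hits, mu = observed_m, alternative = "less"))
  out <- tibble::tibble(
    N = N, K = K, n = n, m = observed_m,
    hypergeom_p = hypergeom_upper_tail(N, K, n, observed_m),
    reps = reps, seed = seed,
    boot_mean = mean(hits), boot_median = stats::median(hits),
    boot_min = min(hits), boot_max = max(hits),
    boot_sd = stats::sd(hits),
    wilcoxon_p = wres$p.value,
    fold_enrichment = observed_m / mean(hits),
    tp_rate = observed_m / n)
  attr(out, "null_hits") <- hits
  class(out) <- c("significance_report", class(out))
  out
}

#' @method glance significance_report
#' @export
glance.significance_report <- function(x, ...) tibble::as_tibble(x)

#' Wilcoxon signed-rank comparison of two rankings of the same genes
#'
#' One-sided paired test that ranking A places the (known) genes earlier
#' (smaller ranks) than ranking B. With `top_fraction` set, only the
#' genes in the top fraction of ranking A are compared (the early part of
#' the list). Zero differences are dropped (Wilcoxon convention); if all
#' differences are zero the test is degenerate and `p = 1` is reported
#' with a flag. The exact distribution is used for up to 25 informative
#' pairs, the normal approximation with continuity correction above.
#'
#' @param ranks_a,ranks_b Paired rank vectors over the same genes.
#' @param top_fraction Optional fraction in `(0, 1]`: restrict to the
#'   `ceiling(q * length)` genes ranked best by `ranks_a`.
#' @return One-row tibble: `p`, `n_pairs`, `n_informative`, `degenerate`.
#' @export
compare_rankings_wilcoxon <- function(ranks_a, ranks_b,
                                      top_fraction = NULL) {
  if (length(ranks_a) != length(ranks_b))
    stop("rank vectors must have equal length")
  if (!is.null(top_fraction)) {
    if (top_fraction <= 0 || top_fraction > 1)
      stop("top_fraction must be in (0, 1]")
    keep <- order(ranks_a)[seq_len(ceiling(top_fraction * length(ranks_a)))]
    ranks_a <- ranks_a[keep]; ranks_b <- ranks_b[keep]
  }
  d <- ranks_a - ranks_b
  informative <- d != 0
  if (!any(informative)) {
    return(tibble::tibble(p = 1, n_pairs = length(d), n_informative = 0L,
                          degenerate = TRUE))
  }
  n_inf <- sum(informative)
  p <- if (n_inf <= 25L) {
    signed_rank_exact_less(d[informative])
  } else {
    suppressWarnings(stats::wilcox.test(
      ranks_a[informative], ranks_b[informative], paired = TRUE,
      alternative = "less", correct = TRUE))$p.value
  }
  tibble::tibble(p = p, n_pairs = length(d),
                 n_informative = n_inf, degenerate = FALSE)
}

# Exact one-sided signed-rank tail P(W+ <= w_obs) by convolution over
# sign flips, valid with tied |d| (midranks scaled to integers) --
# stats::wilcox.test declines the exact path under ties.
signed_rank_exact_less <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))  # midranks doubled: integers
  w_obs <- sum(r2[d > 0])
  total <- sum(r2)
  dist <- c(1, numeric(total))  # dist[w + 1] = #sign patterns with W+ = w
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1L - r)])
    dist <- dist + shifted
  }
  sum(dist[seq_len(w_obs + 1L)]) / 2^length(d)
}
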