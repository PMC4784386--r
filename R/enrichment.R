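# Randomized-tail evaluation rankings and the early-recognition metric
# suite: AUAC, ROC area, enrichment factor, RIE and BEDROC.

#' Build a randomized-tail evaluation ranking
#'
#' Places the prioritized genes at ranks 1..P in their given order and
#' appends the remaining background genes in a uniformly random
#' permutation determined by `seed`. Scoring against the active set then
#' measures how much earlier the prioritized head retrieves actives than
#' chance, without the saturation that affects metrics computed on a
#' small prioritized set alone.
#'
#' @param prioritized Ranked-list tibble or character vector (may be
#'   empty); must be a subset of `background`.
#' @param background Character vector: the full gene universe (size N).
#' @param actives Character vector: known disease genes (the flagged set).
#' @param seed Integer seed for the tail permutation.
#' @return Tibble of class `evaluation_ranking`: `rank`, `gene_id`,
#'   `active`; attributes `n_prioritized` and `seed`.
#' @export
build_evaluation_ranking <- function(prioritized, background, actives,
                                     seed = 1L) {
  head_genes <- ranked_genes(prioritized)
  if (anyDuplicated(background)) stop("background gene ids must be unique")
  outside <- setdiff(head_genes, background)
  if (length(outside) > 0L)
    stop("prioritized gene(s) outside the background: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  tail_genes <- setdiff(background, head_genes)
  tail_genes <- withr::with_seed(seed, sample(tail_genes))
  ordering <- c(head_genes, tail_genes)
  out <- tibble::tibble(
    rank = seq_along(ordering), gene_id = ordering,
    active = ordering %in% actives)
  attr(out, "n_prioritized") <- length(head_genes)
  attr(out, "seed") <- seed
  class(out) <- c("evaluation_ranking", class(out))
  out
}

active_relative_ranks <- function(ev) {
  x <- ev$rank[ev$active] / nrow(ev)
  if (length(x) == 0L) stop("no active genes in the ranking")
  x
}

#' Area under the accumulation curve
#'
#' `AUAC = 1 - mean(x_i)` with `x_i = r_i / N` the relative ranks of the
#' actives: the probability that an active is ranked before a uniformly
#' random gene.
#'
#' @param ev An [build_evaluation_ranking()] tibble (any tibble with
#'   `rank` and `active` works).
#' @return AUAC in `[0, 1)`.
#' @export
auac <- function(ev) {
  1 - mean(active_relative_ranks(ev))
}

#' Area under the ROC curve from the accumulation curve
#'
#' `ROC = AUAC / R_i - R_a / (2 R_i)` with `R_a = n/N` the active ratio
#' and `R_i = (N - n)/N` the inactive ratio: the probability an active is
#' ranked earlier than an inactive.
#'
#' @inheritParams auac
#' @return ROC area.
#' @export
roc_area <- function(ev) {
  n <- sum(ev$active); N <- nrow(ev)
  if (n == N) stop("all genes active: ROC undefined")
  ra <- n / N; ri <- (N - n) / N
  auac(ev) / ri - ra / (2 * ri)
}

#' Enrichment factor at a top fraction
#'
#' `EF = (m / n_top) / (M / N)`: the hit rate in the top `chi` fraction
#' relative to the background hit rate. Maximum `1/chi` when
#' `chi >= M/N` (all actives fit in the fraction), `N/M` otherwise;
#' minimum 0.
#'
#' @inheritParams auac
#' @param chi Top fraction in `(0, 1]`; the top size is `round(chi * N)`.
#' @return The enrichment factor.
#' @export
enrichment_factor <- function(ev, chi) {
  if (chi <= 0 || chi > 1) stop("chi must be in (0, 1]")
  N <- nrow(ev); M <- sum(ev$active)
  n_top <- round(chi * N)
  if (n_top < 1L) stop("top fraction contains no genes")
  m <- sum(ev$active[ev$rank <= n_top])
  (m / n_top) / (M / N)
}

#' Exponential weight alpha for a top fraction of interest
#'
#' The weight parameter tying RIE/BEDROC to the fraction `chi` where early
#' recognition matters: `alpha = -ln(0.2) / chi` (about 80% of the
#' exponential weight falls inside the fraction). The four canonical
#' fractions 1%/5%/10%/20% return the conventional one-decimal values
#' 160.9, 32.2, 16.1 and 8.
#'
#' @param chi Top fraction in `(0, 1)`.
#' @return Alpha.
#' @export
alpha_for_fraction <- function(chi) {
  if (any(chi <= 0 | chi >= 1)) stop("chi must be in (0, 1)")
  canonical <- c(`0.01` = 160.9, `0.05` = 32.2, `0.1` = 16.1, `0.2` = 8)
  vapply(chi, function(x) {
    key <- names(canonical)[vapply(as.numeric(names(canonical)),
                                   function(v) isTRUE(all.equal(v, x)),
                                   logical(1L))]
    if (length(key) == 1L) canonical[[key]] else -log(0.2) / x
  }, numeric(1L))
}

#' Robust initial enhancement and BEDROC
#'
#' `RIE` is the exponentially weighted sum of active relative ranks over
#' its expectation under a uniform rank distribution:
#' `RIE = sum(exp(-alpha * x_i)) / [(n/N) (1 - exp(-alpha)) /
#' (exp(alpha/N) - 1)]`. `RIE_min`/`RIE_max` are attained with all
#' actives at the very end/beginning of the list, and
#' `BEDROC = (RIE - RIE_min) / (RIE_max - RIE_min)` rescales RIE onto
#' `[0, 1]`.
#'
#' @inheritParams auac
#' @param alpha Positive exponential weight (see [alpha_for_fraction()]).
#' @return One-row tibble: `alpha`, `rie`, `rie_min`, `rie_max`,
#'   `bedroc`.
#' @export
rie_bedroc <- function(ev, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  N <- nrow(ev); n <- sum(ev$active)
  if (n == 0L) stop("no active genes in the ranking")
  if (n == N) stop("all genes active: BEDROC undefined")
  x <- active_relative_ranks(ev)
  ra <- n / N
  denom <- ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- sum(exp(-alpha * x)) / denom
  rie_min <- (1 - exp(alpha * ra)) / (ra * (1 - exp(alpha)))
  rie_max <- (1 - exp(-alpha * ra)) / (ra * (1 - exp(-alpha)))
  tibble::tibble(alpha = alpha, rie = rie, rie_min = rie_min,
                 rie_max = rie_max,
                 bedroc = (rie - rie_min) / (rie_max - rie_min))
}

#' Full enrichment / early-recognition metric report
#'
#' AUAC and ROC area, plus EF, RIE (with its bounds) and BEDROC at the
#' four canonical top fractions 1%, 5%, 10% and 20%.
#'
#' @inheritParams auac
#' @param fractions Top fractions to evaluate (default the canonical
#'   four).
#' @return Long tibble of class `metric_report` with columns `metric`,
#'   `fraction` (`NA` for the overall metrics), `alpha` and `value`.
#' @export
metric_report <- function(ev, fractions = c(0.01, 0.05, 0.1, 0.2)) {
  overall <- tibble::tibble(
    metric = c("auac", "roc"), fraction = NA_real_, alpha = NA_real_,
    value = c(auac(ev), roc_area(ev)))
  per_fraction <- purrr::map_dfr(fractions, function(chi) {
    a <- alpha_for_fraction(chi)
    rb <- rie_bedroc(ev, a)
    tibble::tibble(
      metric = c("ef", "rie", "rie_min", "rie_max", "bedroc"),
      fraction = chi, alpha = a,
      value = c(enrichment_factor(ev, chi), rb$rie, rb$rie_min,
                rb$rie_max, rb$bedroc))
  })
  out <- dplyr::bind_rows(overall, per_fraction)
  class(out) <- c("metric_report", class(out))
  out
}

#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) tibble::as_tibble(x)

#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  wide <- x[x$metric %in% c("auac", "roc") |
              (x$metric == "bedroc" & !is.na(x$fraction)), , drop = FALSE]
  key <- ifelse(is.na(wide$fraction), wide$metric,
                sprintf("%s_%g", wide$metric, wide$fraction))
  tibble::as_tibble(as.list(stats::setNames(wide$value, key)))
}

#' Accumulation curve of an evaluation ranking
#'
#' Fraction of actives retrieved as a function of the fraction of the
#' ranked list screened.
#'
#' @param object An `evaluation_ranking` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_ranking
#' @export
autoplot.evaluation_ranking <- function(object, ...) {
  df <- tibble::tibble(
    screened = object$rank / nrow(object),
    recovered = cumsum(object$active) / sum(object$active))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$screened,
                                   y = .data$recovered)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "fraction of ranked list screened",
                  y = "fraction of known genes recovered") +
    ggplot2::theme_minimal()
}
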