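test_that("rank desirability is linear with the stated endpoints", {
  expect_equal(rank_desirability(1L, 500L), 1)
  expect_equal(rank_desirability(500L, 500L), 0)
  expect_equal(rank_desirability(251L, 500L), (500 - 251) / 499)
  expect_equal(rank_desirability(251L, 500L), 0.499, tolerance = 1e-3)
  ranks <- 1:100
  expect_true(all(diff(rank_desirability(ranks, 100L)) < 0))
})

test_that("ensemble desirability hits 1 and 0 at unanimous best/worst ranks", {
  # two genes engineered so every ranker agrees on the order
  withr::with_seed(2, m <- matrix(rnorm(5 * 20, sd = 0.2), 5))
  m[1, ] <- rep(c(5, -5), each = 10)
  expr <- make_expr(m, labels = two_group_labels(10, 10))
  ens <- consensus_feature_ranking(expr)
  sc <- ensemble_scores(ens)
  expect_equal(sc$d_rank_mean[sc$gene_id == "g001"], 1)
  expect_true(all(ens$d_rank >= 0 & ens$d_rank <= 1))
  worst <- ens |>
    dplyr::filter(.data$rank_position == max(.data$rank_position))
  expect_true(all(worst$d_rank == 0))
})

test_that("ensemble score is invariant to ranker order", {
  expr <- informative_fixture(seed = 8)
  r <- default_rankers()
  a <- ensemble_scores(consensus_feature_ranking(expr, rankers = r))
  b <- ensemble_scores(consensus_feature_ranking(expr, rankers = rev(r)))
  expect_equal(a, b[match(a$gene_id, b$gene_id), ])
})

test_that("classifier consensus desirability follows (nrel-1)/(n_class-1)", {
  expect_equal(classifier_consensus_score(1, 13), 0)
  expect_equal(classifier_consensus_score(13, 13), 1)
  expect_equal(classifier_consensus_score(7, 13), 0.5)
  expect_error(classifier_consensus_score(0, 13), "nrel")
  expect_error(classifier_consensus_score(1, 1), "n_class")
  expect_error(classifier_consensus_score(5, 3), "exceed")
})

test_that("a separable problem yields perfect training metrics and validity", {
  withr::with_seed(3, {
    m <- matrix(rnorm(10 * 32, sd = 0.2), 10)
    m[1, ] <- rep(c(4, -4), each = 16)
    m[2, ] <- rep(c(-4, 4), each = 16)
  })
  expr <- make_expr(m, labels = two_group_labels(16, 16))
  panel <- evaluate_classifier_panel(
    expr, classifiers = default_classifiers()[c("lasso_logistic", "cart")],
    seed = 2)
  expect_equal(panel$acc_train, c(1, 1))
  expect_equal(panel$se_train, c(1, 1))
  expect_equal(panel$sp_train, c(1, 1))
  expect_true(all(panel$valid))
  expect_true(all(vapply(panel$genes, length, 1L) >= 1))
})

test_that("any metric at or below 0.6 invalidates a classifier", {
  # constant-prediction classifier: specificity 0 on every split
  constant <- function(x, y) {
    list(predict = function(newx) rep("case", nrow(newx)),
         features = colnames(x)[1])
  }
  expr <- informative_fixture(n_genes = 10, n_per_group = 8, seed = 4)
  panel <- evaluate_classifier_panel(expr, classifiers = list(const = constant),
                                     seed = 1)
  expect_equal(panel$sp_train, 0)
  expect_false(panel$valid)
})

test_that("label-permuted data drives accuracy to chance and validity down", {
  d <- small_planted(seed = 6)
  top <- d$expr[1:40, ]
  acc <- valid <- numeric(0)
  for (s in 1:6) {
    perm <- d$labels
    perm$group <- withr::with_seed(300 + s, sample(perm$group))
    panel <- evaluate_classifier_panel(
      top, perm, classifiers = default_classifiers()[c("lasso_logistic", "cart")],
      seed = s)
    acc <- c(acc, panel$acc_test)
    valid <- c(valid, panel$valid)
  }
  expect_lt(mean(acc), 0.75)  # majority class is 0.5 here
  expect_lt(mean(valid), 0.25)
})

test_that("MLrel fuses ensemble and classifier desirabilities over the valid union", {
  ens <- tibble::tibble(
    gene_id = rep(c("a", "b", "c", "d"), 2),
    ranker = rep(c("r1", "r2"), each = 4),
    rank_position = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
    d_rank = rank_desirability(c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L), 4L))
  panel <- tibble::tibble(
    classifier = c("c1", "c2", "c3"),
    genes = list(c("a", "b"), c("a", "c"), c("x")),
    valid = c(TRUE, TRUE, FALSE))
  out <- ml_relevance_ranking(ens, panel)
  # universe = union of valid subsets only; "d" and invalid-only "x" absent
  expect_setequal(out$gene_id, c("a", "b", "c"))
  # a: D = 1, in both valid classifiers -> d_class 1 -> MLrel 1
  expect_equal(out$score[out$gene_id == "a"], 1)
  # b: D = 2/3, nrel 1 of 2 -> d_class 0 -> MLrel 1/3
  expect_equal(out$score[out$gene_id == "b"], (2 / 3) / 2)
  expect_equal(out$gene_id[1], "a")
  expect_true(all(out$score >= 0 & out$score <= 1))
})

test_that("genes selected by no valid classifier are excluded; no valid classifiers errors", {
  ens <- tibble::tibble(gene_id = c("a", "b"), ranker = "r1",
                        rank_position = 1:2,
                        d_rank = rank_desirability(1:2, 2L))
  none <- tibble::tibble(classifier = "c1", genes = list("a"), valid = FALSE)
  expect_error(ml_relevance_ranking(ens, none), "no valid")
})

test_that("planted discriminative genes outscore decoys in MLrel", {
  d <- small_planted(seed = 9)
  mr <- mrmr_select(d$expr, k = 40, labels = d$labels)
  sub <- d$expr[match(mr$gene_id, d$expr$gene_id), ]
  ens <- consensus_feature_ranking(sub, d$labels)
  panel <- evaluate_classifier_panel(
    sub, d$labels,
    classifiers = default_classifiers()[c("lasso_logistic", "elastic_net", "cart")],
    seed = 11)
  ml <- ml_relevance_ranking(ens, panel)
  planted <- d$truth$gene_id[d$truth$de]
  in_planted <- ml$gene_id %in% planted
  expect_gt(mean(ml$score[in_planted]), mean(ml$score[!in_planted]))
})
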