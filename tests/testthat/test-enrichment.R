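test_that("prioritized genes occupy the head in order; tails are seeded permutations", {
  background <- sprintf("b%03d", 1:200)
  prioritized <- background[c(5, 1, 9, 100:146)]
  actives <- background[1:20]
  ev <- build_evaluation_ranking(prioritized, background, actives, seed = 4)
  expect_equal(nrow(ev), 200L)
  expect_equal(ev$gene_id[1:50], prioritized)
  expect_equal(sum(ev$active), 20L)
  expect_identical(build_evaluation_ranking(prioritized, background,
                                            actives, seed = 4), ev)
  ev2 <- build_evaluation_ranking(prioritized, background, actives, seed = 5)
  expect_false(identical(ev$gene_id, ev2$gene_id))
  expect_error(build_evaluation_ranking("zzz", background, actives),
               "outside the background")
})

test_that("a fixed tail gene has the uniform-permutation expected rank", {
  background <- sprintf("b%03d", 1:60)
  prioritized <- background[1:10]
  probe <- "b042"
  ranks <- vapply(1:3000, function(s) {
    ev <- build_evaluation_ranking(prioritized, background, "b001", seed = s)
    ev$rank[ev$gene_id == probe]
  }, integer(1))
  expected <- 10 + (60 - 10 + 1) / 2          # 35.5
  se <- sqrt((50^2 - 1) / 12) / sqrt(3000)
  expect_lt(abs(mean(ranks) - expected), 3 * se)
})

test_that("AUAC equals one minus the mean relative active rank", {
  background <- sprintf("b%03d", 1:100)
  ev <- build_evaluation_ranking(background[1], background, background[1],
                                 seed = 1)
  expect_equal(auac(ev), 0.99)
})

test_that("random rankings score near one half on AUAC and ROC", {
  vals <- withr::with_seed(77, vapply(1:200, function(s) {
    ev <- random_ranking(1000, 50, seed = s)
    c(auac(ev), roc_area(ev))
  }, numeric(2)))
  expect_gt(mean(vals[1, ]), 0.48); expect_lt(mean(vals[1, ]), 0.52)
  expect_gt(mean(vals[2, ]), 0.48); expect_lt(mean(vals[2, ]), 0.52)
})

test_that("the closed-form ROC agrees with the rank-based U-statistic area", {
  for (seed in c(3, 12, 25)) {
    ev <- withr::with_seed(seed, random_ranking(500, 40, seed = seed))
    # trapezoidal ROC area = Mann-Whitney statistic / (n_act * n_inact)
    act_ranks <- ev$rank[ev$active]
    n1 <- sum(ev$active); n0 <- nrow(ev) - n1
    u <- sum(nrow(ev) + 1 - act_ranks) - n1 * (n1 + 1) / 2
    expect_equal(roc_area(ev), u / (n1 * n0), tolerance = 1 / nrow(ev))
  }
})

test_that("enrichment factor reproduces hand-computed values and bounds", {
  background <- sprintf("b%03d", 1:100)
  actives <- background[seq(1, 19, 2)]  # 10 actives, 5 in the top 10
  ev <- tibble::tibble(rank = 1:100, gene_id = background,
                       active = background %in% actives)
  expect_equal(enrichment_factor(ev, 0.1), 5)

  all_top <- tibble::tibble(rank = 1:100, gene_id = background,
                            active = c(rep(TRUE, 10), rep(FALSE, 90)))
  expect_equal(enrichment_factor(all_top, 0.2), 5)      # = 1/chi maximum
  none_top <- tibble::tibble(rank = 1:100, gene_id = background,
                             active = c(rep(FALSE, 90), rep(TRUE, 10)))
  expect_equal(enrichment_factor(none_top, 0.2), 0)
})

test_that("EF never exceeds its stated maximum over random configurations", {
  for (seed in 1:10) {
    ev <- withr::with_seed(seed, random_ranking(300, 30, seed = seed))
    for (chi in c(0.05, 0.1, 0.2, 0.5)) {
      ef <- enrichment_factor(ev, chi)
      expect_gte(ef, 0)
      expect_lte(ef, min(1 / chi, nrow(ev) / sum(ev$active)) + 1e-12)
    }
  }
})

test_that("the alpha mapping reproduces the canonical printed values", {
  expect_equal(alpha_for_fraction(0.01), 160.9)
  expect_equal(alpha_for_fraction(0.05), 32.2)
  expect_equal(alpha_for_fraction(0.10), 16.1)
  expect_equal(alpha_for_fraction(0.20), 8)
  # non-canonical fractions use the exact rule
  expect_equal(alpha_for_fraction(0.3), -log(0.2) / 0.3)
  expect_error(alpha_for_fraction(1.5), "\\(0, 1\\)")
})

test_that("RIE matches the hand-evaluated toy example", {
  background <- sprintf("b%d", 1:8)
  ev <- tibble::tibble(rank = 1:8, gene_id = background,
                       active = c(TRUE, FALSE, FALSE, FALSE, TRUE,
                                  FALSE, FALSE, FALSE))
  rb <- rie_bedroc(ev, alpha = 8)
  numer <- exp(-1) + exp(-5)
  denom <- 0.25 * (1 - exp(-8)) / (exp(1) - 1)
  expect_equal(rb$rie, numer / denom, tolerance = 1e-12)
  expect_equal(rb$rie, 2.576, tolerance = 1e-3)
})

test_that("BEDROC is exactly 1 and 0 at the list extremes", {
  N <- 150; n <- 12
  ids <- sprintf("b%03d", 1:N)
  best <- tibble::tibble(rank = 1:N, gene_id = ids,
                         active = c(rep(TRUE, n), rep(FALSE, N - n)))
  worst <- tibble::tibble(rank = 1:N, gene_id = ids,
                          active = c(rep(FALSE, N - n), rep(TRUE, n)))
  for (alpha in c(8, 16.1, 32.2, 160.9)) {
    expect_equal(rie_bedroc(best, alpha)$bedroc, 1, tolerance = 1e-9)
    expect_equal(rie_bedroc(worst, alpha)$bedroc, 0, tolerance = 1e-9)
  }
})

test_that("promoting any single active never decreases RIE or BEDROC", {
  withr::with_seed(41, {
    for (trial in 1:5) {
      N <- 80
      act_pos <- sort(sample(2:N, 8))
      ids <- sprintf("b%03d", 1:N)
      ev <- tibble::tibble(rank = 1:N, gene_id = ids,
                           active = seq_len(N) %in% act_pos)
      rb <- rie_bedroc(ev, 16.1)
      moved <- act_pos
      pick <- sample(seq_along(act_pos), 1)
      target <- sample(setdiff(seq_len(act_pos[pick] - 1),
                               act_pos), 1)
      moved[pick] <- target
      ev2 <- tibble::tibble(rank = 1:N, gene_id = ids,
                            active = seq_len(N) %in% moved)
      rb2 <- rie_bedroc(ev2, 16.1)
      expect_gte(rb2$rie, rb$rie)
      expect_gte(rb2$bedroc, rb$bedroc)
    }
  })
})

test_that("BEDROC approaches the ROC area as alpha tends to zero", {
  for (seed in c(6, 19)) {
    ev <- withr::with_seed(seed, random_ranking(400, 30, seed = seed))
    expect_equal(rie_bedroc(ev, 0.001)$bedroc, roc_area(ev),
                 tolerance = 0.01)
  }
})

test_that("RIE equals the permutation-expectation ratio of the weighted sum", {
  withr::with_seed(55, {
    N <- 200; n <- 10; alpha <- 16.1
    act <- sort(sample(N, n))
    ids <- sprintf("b%03d", 1:N)
    ev <- tibble::tibble(rank = 1:N, gene_id = ids,
                         active = seq_len(N) %in% act)
    obs <- sum(exp(-alpha * act / N))
    perm <- vapply(1:10000, function(i)
      sum(exp(-alpha * sample(N, n) / N)), numeric(1))
  })
  ratio <- obs / mean(perm)
  se_ratio <- obs * sd(perm) / (mean(perm)^2 * sqrt(10000))
  expect_lt(abs(rie_bedroc(ev, alpha)$rie - ratio), 2 * se_ratio + 1e-9)
})

test_that("the metric report is complete, consistent and serializable", {
  ids <- sprintf("b%03d", 1:300)
  ev <- tibble::tibble(rank = 1:300, gene_id = ids,
                       active = c(rep(TRUE, 15), rep(FALSE, 285)))
  rep_tbl <- metric_report(ev)
  expect_setequal(unique(rep_tbl$metric),
                  c("auac", "roc", "ef", "rie", "rie_min", "rie_max", "bedroc"))
  bed <- rep_tbl$value[rep_tbl$metric == "bedroc"]
  expect_equal(bed, rep(1, 4), tolerance = 1e-9)  # perfect ranking

  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tidy(rep_tbl), f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$value, rep_tbl$value)

  ef_null <- withr::with_seed(99, vapply(1:100, function(s) {
    enrichment_factor(random_ranking(300, 15, seed = s), 0.1)
  }, numeric(1)))
  expect_equal(mean(ef_null), 1, tolerance = 0.25)
})
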