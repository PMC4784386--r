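test_that("adjacency is |cor|^beta with zero diagonal and symmetric", {
  withr::with_seed(3, z <- rnorm(10))
  m <- rbind(z, z * 2, -z + rnorm(10, sd = 1e-8), rnorm(10))
  expr <- make_expr(m)
  net <- build_adjacency(expr, beta = 6)
  a <- net$adjacency
  expect_equal(a[1, 2], 1)               # perfect positive correlation
  expect_equal(a[1, 3], 1, tolerance = 1e-4)  # perfect negative (unsigned)
  expect_true(isSymmetric(a))
  expect_equal(unname(diag(a)), rep(0, 4))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(net$node_k, rowSums(a))
})

test_that("a correlation of 0.5 at beta 6 gives adjacency 0.015625", {
  expect_equal(abs(0.5)^6, 0.015625)
  # through the full path: build two genes with known correlation
  withr::with_seed(8, {
    n <- 1e5
    z <- rnorm(n); e <- rnorm(n)
    g2 <- 0.5 * z + sqrt(1 - 0.25) * e
  })
  m <- rbind(z, g2, rnorm(n))
  net <- build_adjacency(make_expr(m), beta = 6)
  expect_lt(abs(net$adjacency[1, 2] - 0.015625), 2e-3)
})

test_that("zero-variance genes are rejected by name", {
  m <- rbind(rnorm(6), rep(2, 6))
  expect_error(build_adjacency(make_expr(m)), "g002")
})

test_that("an exact power-law degree distribution fits with R-squared 1", {
  k <- rep(c(2, 4, 8, 16), c(64, 16, 4, 1))
  r2 <- suppressWarnings(scale_free_fit(k, n_bins = 8))  # lm: perfect fit
  expect_equal(as.numeric(r2), 1, tolerance = 1e-9)
  expect_equal(attr(r2, "slope"), -2, tolerance = 1e-9)
})

test_that("degenerate and non-scale-free connectivities are handled", {
  expect_error(scale_free_fit(rep(3, 10)), "degenerate")
  withr::with_seed(13, {
    dense <- build_adjacency(make_expr(matrix(rnorm(60 * 20), 60)), beta = 2)
    power_k <- rep(2^(1:6), round(200 * 2^(-(1:6))))
  })
  expect_gt(as.numeric(scale_free_fit(power_k, n_bins = 12)),
            as.numeric(scale_free_fit(dense, n_bins = 12)))
})

test_that("TOM is symmetric, bounded, and maximal for a complete block", {
  n <- 6
  a <- matrix(1, n, n); diag(a) <- 0
  net <- consensusprio:::new_coexpr_network(a, beta = 6)
  tom <- topological_overlap(net)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom[1, 2], 1)
})

test_that("planted correlation blocks are recovered across seeds", {
  for (seed in 1:10) {
    d <- small_planted(seed = seed)
    net <- build_adjacency(d$expr[, c(TRUE, d$labels$group == "case")],
                           beta = 6)
    mods <- detect_modules(net, min_size = 15)
    skip_if_not_installed("mclust")
    ari <- mclust::adjustedRandIndex(mods$module, d$truth$module)
    expect_gte(ari, 0.9)
  }
})

test_that("uniform perfect correlation collapses to a single module", {
  a <- matrix(1, 30, 30); diag(a) <- 0
  rownames(a) <- colnames(a) <- sprintf("g%03d", 1:30)
  net <- consensusprio:::new_coexpr_network(a, beta = 6)
  mods <- detect_modules(net, min_size = 5)
  expect_equal(unique(mods$module), 1L)
})

test_that("independent noise genes stay unassigned", {
  withr::with_seed(31, m <- matrix(rnorm(120 * 20), 120))
  net <- build_adjacency(make_expr(m), beta = 6)
  mods <- detect_modules(net, min_size = 5)
  expect_equal(unique(mods$module), 0L)
})

test_that("module statistics match complete-graph expectations", {
  a <- matrix(0, 8, 8)
  a[1:5, 1:5] <- 1
  diag(a) <- 0
  rownames(a) <- colnames(a) <- sprintf("g%03d", 1:8)
  net <- consensusprio:::new_coexpr_network(a, beta = 6)
  modules <- tibble::tibble(gene_id = rownames(a),
                            module = rep(c(1L, 0L), c(5L, 3L)))
  de <- tibble::tibble(gene_id = rownames(a),
                       log_diff = c(0.1, -0.3, 0, 0, 0.2, 1, 1, 1))
  st <- module_statistics(net, modules, de)
  expect_equal(st$n, 5L)
  expect_equal(st$mean_k, 4)
  expect_equal(st$mean_k_intra, 4)
  expect_equal(st$mean_log_diff, mean(c(0.1, -0.3, 0, 0, 0.2)))
})

test_that("two-gene module log-difference averaging is plain arithmetic", {
  a <- matrix(0.5, 4, 4); diag(a) <- 0
  rownames(a) <- colnames(a) <- c("u", "v", "w", "x")
  net <- consensusprio:::new_coexpr_network(a, beta = 6)
  modules <- tibble::tibble(gene_id = c("u", "v", "w", "x"),
                            module = c(1L, 1L, 0L, 0L))
  de <- tibble::tibble(gene_id = c("u", "v", "w", "x"),
                       log_diff = c(0.1, -0.3, 9, 9))
  expect_equal(module_statistics(net, modules, de)$mean_log_diff, -0.1)
})

test_that("intramodular connectivity never exceeds whole-network connectivity", {
  d <- small_planted(seed = 3)
  net <- build_adjacency(d$expr[, c(TRUE, d$labels$group == "case")], beta = 6)
  mods <- detect_modules(net, min_size = 15)
  st <- module_statistics(net, mods)
  expect_true(all(st$mean_k_intra <= st$mean_k + 1e-12))
})

test_that("module merit reproduces published-scale fold-enrichments", {
  expect_equal(module_merit(103, 134, 1437, 8477), 4.53, tolerance = 0.005 / 4.53)
  expect_equal(module_merit(42, 56, 1437, 8477), 4.42, tolerance = 0.005 / 4.42)
  expect_equal(module_merit(50, 50, 8477, 8477), 1)
  expect_error(module_merit(10, 0, 100, 1000), "nonzero")
  expect_error(module_merit(200, 100, 150, 1000), "exceed")
})

test_that("merit exceeds 1 exactly when the module is over-represented", {
  # module holds 10% of background but 20% of selected genes
  expect_gt(module_merit(20, 100, 100, 1000), 1)
  # proportional representation
  expect_equal(module_merit(10, 100, 100, 1000), 1)
  expect_lt(module_merit(5, 100, 100, 1000), 1)
})
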