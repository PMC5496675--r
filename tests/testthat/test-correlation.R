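test_that("pearson correlation of binary columns equals the phi coefficient", {
  # contingency a=11 (both 1), b=9, c=9, d=71 over n=100
  a <- 11; b <- 9; c <- 9; d <- 71
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  X <- cbind(x = x, y = y)
  C <- pearson_matrix(X)
  phi <- (a * d - b * c) /
    sqrt((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(C["x", "y"], phi, tolerance = 1e-12)
  expect_equal(C, t(C))
  expect_equal(diag(C), c(x = 1, y = 1))
})

test_that("identical columns give r = 1, balanced complements r = -1", {
  x <- rep(c(1, 0), 50)
  expect_equal(pearson_matrix(cbind(a = x, b = x))["a", "b"], 1)
  expect_equal(pearson_matrix(cbind(a = x, b = 1 - x))["a", "b"], -1)
})

test_that("pearson_matrix agrees with stats::cor and ignores row order", {
  m <- planted_model(n_tf = 6, truth_edges = 5, n_segments = 400, seed = 8)
  bm <- simulate_binding(m)
  X <- as.matrix(bm$X)
  expect_equal(pearson_matrix(bm), stats::cor(X), tolerance = 1e-12)
  perm <- sample(nrow(X))
  expect_equal(pearson_matrix(X[perm, ]), pearson_matrix(X),
               tolerance = 1e-12)
})

test_that("constant columns yield NA correlations with a warning", {
  X <- cbind(a = rep(c(0, 1), 10), b = rep(0, 20), c = rep(c(1, 0), 10))
  expect_warning(C <- pearson_matrix(X), "constant")
  expect_true(all(is.na(C["b", ])))
  expect_true(all(is.na(C[, "b"])))
  expect_equal(C["a", "c"], -1)
})

test_that("cluster_samples merges the identical pair first and matches a brute-force oracle", {
  x <- rep(c(1, 0), 30)
  X <- cbind(a = x, b = x, c = 1 - x)
  suppressWarnings(C <- pearson_matrix(X))
  hc <- cluster_samples(C)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
  expect_equal(hc$height[1], 0)

  # two perfect blocks -> two top-level clusters
  X4 <- cbind(a = x, b = x, c = 1 - x, d = 1 - x)
  hc4 <- cluster_samples(pearson_matrix(X4))
  expect_setequal(unname(stats::cutree(hc4, 2)),
                  c(1, 1, 2, 2))
  expect_equal(unname(stats::cutree(hc4, 2)[c("a", "b")]), c(1, 1))

  set.seed(9)
  R <- stats::cov2cor(crossprod(matrix(rnorm(60), 10, 6)))
  dimnames(R) <- list(letters[1:6], letters[1:6])
  hc6 <- cluster_samples(R, linkage = "complete")
  expect_equal(sort(hc6$height), agglom_heights_oracle(1 - R),
               tolerance = 1e-10)
})

test_that("correlation_graph respects thresholds, budgets and NA columns", {
  C <- matrix(c(
    1, 0.6, 0.2, 0.55,
    0.6, 1, 0.3, 0.1,
    0.2, 0.3, 1, 0.4,
    0.55, 0.1, 0.4, 1
  ), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  net <- correlation_graph(C, threshold = 0.55)
  expect_equal(tidy(net)$node_a, c("a", "a"))
  expect_equal(tidy(net)$node_b, c("b", "d"))

  expect_equal(n_edges(correlation_graph(C, threshold = 1.0)), 0)
  expect_equal(n_edges(correlation_graph(C, threshold = 0.05)), 6)

  budget2 <- correlation_graph(C, edge_budget = 2)
  expect_true(all(has_edge(budget2, c("a", "a"), c("b", "d"))))

  expect_error(correlation_graph(C), "exactly one")
  expect_error(correlation_graph(C, threshold = 0.5, edge_budget = 3),
               "exactly one")

  # edge count is non-increasing in the threshold
  counts <- vapply(seq(0, 1, by = 0.1), function(th) {
    n_edges(correlation_graph(C, threshold = th))
  }, 0L)
  expect_true(all(diff(counts) <= 0))

  # NA columns contribute no edges but stay in the node universe
  Cna <- C; Cna["c", ] <- Cna[, "c"] <- NA; Cna["c", "c"] <- NA
  net_na <- correlation_graph(Cna, threshold = 0.5)
  expect_false(any(grepl("c", c(tidy(net_na)$node_a, tidy(net_na)$node_b))))
  expect_true("c" %in% net_na$nodes)
})
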