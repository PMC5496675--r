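test_that("symmetrize averages directed influences and is idempotent", {
  vals <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  vals["a", "b"] <- 0.8; vals["b", "a"] <- 0.2
  dm <- tfnet:::new_dependence_matrix(vals, "regression", symmetric = FALSE)
  sym <- symmetrize(dm)
  expect_true(sym$symmetric)
  expect_equal(sym$values["a", "b"], 0.5)
  expect_equal(sym$values["b", "a"], 0.5)
  expect_equal(symmetrize(sym)$values, sym$values)

  set.seed(81)
  rnd <- matrix(runif(25), 5, 5,
                dimnames = list(paste0("v", 1:5), paste0("v", 1:5)))
  dm2 <- tfnet:::new_dependence_matrix(rnd, "regression", symmetric = FALSE)
  s2 <- symmetrize(dm2)
  expect_equal(s2$values, t(s2$values))
  expect_equal(symmetrize(s2)$values, s2$values)
})

test_that("select_edges applies thresholds and budgets, never self-edges", {
  vals <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  vals["a", "b"] <- vals["b", "a"] <- 0.9
  vals["a", "c"] <- vals["c", "a"] <- -0.7   # ranked by absolute score
  vals["b", "c"] <- vals["c", "b"] <- 0.5
  vals["c", "d"] <- vals["d", "c"] <- 0.1
  diag(vals) <- 100  # huge diagonal must still be ignored
  dm <- tfnet:::new_dependence_matrix(vals, "ggm", symmetric = TRUE)

  expect_equal(n_edges(select_edges(dm, threshold = 101)), 0)
  net <- select_edges(dm, threshold = 0.6)
  expect_equal(nrow(tidy(net)), 2)
  expect_true(all(has_edge(net, c("a", "a"), c("b", "c"))))
  expect_false(any(tidy(net)$node_a == tidy(net)$node_b))

  budget3 <- select_edges(dm, edge_budget = 3)
  expect_true(all(has_edge(budget3, c("a", "a", "b"), c("b", "c", "c"))))
  expect_equal(n_edges(budget3), 3)

  # ties at the cut are all included
  vals2 <- vals
  vals2["b", "c"] <- vals2["c", "b"] <- 0.7
  dm2 <- tfnet:::new_dependence_matrix(vals2, "ggm", symmetric = TRUE)
  expect_equal(n_edges(select_edges(dm2, edge_budget = 2)), 3)

  expect_error(select_edges(dm), "exactly one")
})

test_that("consensus keeps edges by vote count with union/intersection limits", {
  nodes <- c("a", "b", "c", "d")
  n1 <- toy_network(c("a", "b"), c("a", "c"), c("c", "d"), nodes = nodes)
  n2 <- toy_network(c("a", "b"), c("a", "c"), nodes = nodes)
  n3 <- toy_network(c("a", "b"), c("a", "c"), nodes = nodes)
  n4 <- toy_network(c("a", "b"), c("b", "c"), nodes = nodes)
  nets <- list(n1, n2, n3, n4)

  cons3 <- consensus_network(nets, min_support = 3)
  expect_equal(tidy(cons3)$node_a, c("a", "a"))
  expect_equal(tidy(cons3)$node_b, c("b", "c"))
  expect_equal(tidy(cons3)$support, c(4L, 3L))
  expect_equal(cons3$nodes, nodes)  # universe preserved

  union_net <- consensus_network(nets, min_support = 1)
  inter_net <- consensus_network(nets, min_support = 4)
  expect_equal(n_edges(union_net), 4)
  expect_equal(n_edges(inter_net), 1)

  # anti-monotone in min_support
  sizes <- vapply(1:4, function(k) {
    n_edges(consensus_network(nets, min_support = k))
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
  for (k in 1:3) {
    ek <- tidy(consensus_network(nets, min_support = k))
    ek1 <- tidy(consensus_network(nets, min_support = k + 1))
    expect_true(all(
      tfnet:::pair_key(ek1$node_a, ek1$node_b) %in%
        tfnet:::pair_key(ek$node_a, ek$node_b)))
  }

  # support histogram sums to the union of edge sets
  expect_equal(sum(n_edges(union_net)), 4)

  expect_error(consensus_network(nets, min_support = 5), "min_support")
  bad <- toy_network(c("a", "b"), nodes = c("a", "b"))
  expect_error(consensus_network(list(n1, bad), 1), "universe")
})

test_that("prune_isolated removes and counts degree-0 nodes", {
  net <- toy_network(c("a", "b"), nodes = c("a", "b", "c", "d", "e"))
  pr <- prune_isolated(net)
  expect_equal(pr$n_removed, 3)
  expect_equal(pr$network$nodes, c("a", "b"))
  expect_equal(tidy(pr$network), tidy(net))

  full <- toy_network(c("a", "b"), c("b", "c"), c("a", "c"))
  expect_equal(prune_isolated(full)$n_removed, 0)

  empty <- tf_network(nodes = c("x", "y"))
  expect_equal(prune_isolated(empty)$n_removed, 2)
  expect_equal(n_nodes(prune_isolated(empty)$network), 0)
})

test_that("gold-standard annotation labels edges by TF pair, never same-TF pairs", {
  meta <- toy_metadata(c("s1", "s2", "s3", "s4"),
                       tfs = c("LMO2", "GATA2", "GATA2", "TAL1"))
  gold <- gold_standard(c("LMO2", "GATA2"), c("GATA2", "RUNX1"),
                        score = c(800L, 600L),
                        action = c("binding", "other"),
                        action_keyword = "binding")
  net <- toy_network(c("s1", "s2"), c("s2", "s3"), c("s3", "s4"))
  ann <- annotate_with_gold(net, gold, meta)
  e <- tidy(ann)
  # s1:LMO2 - s2:GATA2 is in gold and physical
  expect_setequal(e$annotations[[1]],
                  c("string_high_confidence", "string_physical"))
  # s2/s3 both GATA2: same TF, never labelled
  expect_equal(e$annotations[[2]], character())
  # GATA2-TAL1 absent from gold
  expect_equal(e$annotations[[3]], character())

  expect_error(annotate_with_gold(net, gold, meta[-1, ]), "missing")
})
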