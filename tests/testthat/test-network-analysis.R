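triangle <- function() toy_network(c("a", "b"), c("b", "c"), c("a", "c"))
star4 <- function() toy_network(c("h", "x"), c("h", "y"), c("h", "z"))

test_that("degree distribution covers all nodes including isolated ones", {
  expect_equal(degree_distribution(triangle()),
               tibble::tibble(degree = 2L, n_nodes = 3L))
  expect_equal(degree_distribution(star4()),
               tibble::tibble(degree = c(1L, 3L), n_nodes = c(3L, 1L)))
  with_iso <- toy_network(c("a", "b"), nodes = c("a", "b", "c"))
  dd <- degree_distribution(with_iso)
  expect_equal(dd$n_nodes[dd$degree == 0], 1L)
  expect_equal(sum(dd$n_nodes), n_nodes(with_iso))
})

test_that("graph metrics match brute-force recounts on a random graph", {
  set.seed(91)
  ids <- paste0("n", 1:15)
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), 30)
  net <- tf_network(edges = tibble::tibble(node_a = pairs[pick, 1],
                                           node_b = pairs[pick, 2]),
                    nodes = ids)
  adj <- matrix(0, 15, 15, dimnames = list(ids, ids))
  e <- tidy(net)
  adj[cbind(e$node_a, e$node_b)] <- 1
  adj <- adj + t(adj)
  deg <- rowSums(adj)

  # handshake lemma
  expect_equal(sum(deg), 2 * n_edges(net))

  dd <- degree_distribution(net)
  expect_equal(dd, tibble::tibble(degree = as.integer(names(table(deg))),
                                  n_nodes = as.integer(table(deg))))

  # local clustering via O(n^3) triangle enumeration
  cc <- vapply(ids, function(v) {
    nb <- ids[adj[v, ] == 1]
    if (length(nb) < 2) return(0)
    tri <- 0
    for (i in seq_along(nb)) {
      for (j in seq_along(nb)) {
        if (i < j && adj[nb[i], nb[j]] == 1) tri <- tri + 1
      }
    }
    2 * tri / (length(nb) * (length(nb) - 1))
  }, 0)
  cbd <- clustering_by_degree(net)
  for (k in cbd$degree) {
    expect_equal(cbd$mean_clustering[cbd$degree == k],
                 mean(cc[deg == k]), tolerance = 1e-12)
  }

  # mean neighbour degree recount
  knn_node <- vapply(ids, function(v) {
    nb <- ids[adj[v, ] == 1]
    if (!length(nb)) return(NA_real_)
    mean(deg[nb])
  }, 0)
  mnd <- mean_neighbour_degree(net)
  for (k in mnd$degree) {
    expect_equal(mnd$mean_neighbour_degree[mnd$degree == k],
                 mean(knn_node[deg == k], na.rm = TRUE), tolerance = 1e-12)
  }
})

test_that("clustering and neighbour-degree specialise correctly on canonical graphs", {
  cbd <- clustering_by_degree(triangle())
  expect_equal(cbd$mean_clustering, 1)
  cbd_star <- clustering_by_degree(star4())
  expect_true(all(cbd_star$mean_clustering == 0))

  # star: centre degree 3 has neighbours of degree 1 and vice versa
  mnd <- mean_neighbour_degree(star4())
  expect_equal(mnd$mean_neighbour_degree[mnd$degree == 3], 1)
  expect_equal(mnd$mean_neighbour_degree[mnd$degree == 1], 3)

  # k-regular graph: {k: k}
  ring <- toy_network(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d"))
  mnd_ring <- mean_neighbour_degree(ring)
  expect_equal(mnd_ring, tibble::tibble(degree = 2L,
                                        mean_neighbour_degree = 2,
                                        n_nodes = 4L))
})

test_that("first-neighbour profiles count neighbours by cell type", {
  meta <- toy_metadata(c("s1", "s2", "s3", "s4"),
                       cell_types = c("HSPC", "HSPC", "Ery", "HSPC"))
  net <- toy_network(c("s1", "s2"), c("s1", "s3"), c("s1", "s4"))
  prof <- first_neighbour_profile(net, meta)
  s1 <- prof[prof$sample_id == "s1", ]
  expect_equal(setNames(s1$n_neighbours, s1$cell_type),
               c(Ery = 1L, HSPC = 2L))
  # totals equal degrees
  totals <- prof |> dplyr::count(sample_id, wt = n_neighbours, name = "deg")
  deg <- tfnet:::node_degrees(net)
  expect_equal(setNames(totals$deg, totals$sample_id), deg[deg > 0])
  # isolated nodes yield no rows
  iso_net <- toy_network(c("s1", "s2"), nodes = c("s1", "s2", "s3"))
  expect_false("s3" %in% first_neighbour_profile(iso_net, meta)$sample_id)
  expect_error(first_neighbour_profile(net, meta[1:2, ]), "missing")
})

test_that("within-block neighbours dominate in a planted block model", {
  m <- planted_model(n_tf = 16, truth_edges = 0L, n_segments = 1500,
                     coupling_strength = 0, cell_types = 2L,
                     block_coupling = 0.35, seed = 17)
  bm <- simulate_binding(m)
  net <- select_edges(ggm_scores(bm), edge_budget = 24)
  prof <- first_neighbour_profile(net, model_metadata(m) |>
                                    dplyr::rename(sample_id = sample_id))
  meta <- model_metadata(m)
  ct_of <- setNames(meta$cell_type, meta$sample_id)
  within <- sum(prof$n_neighbours[prof$cell_type ==
                                    ct_of[prof$sample_id]])
  between <- sum(prof$n_neighbours) - within
  expect_gt(within, between)
})

test_that("subnetwork extraction closes seeds under first neighbours", {
  meta <- toy_metadata(c("s1", "s2", "s3", "s4"),
                       tfs = c("GATA1", "GATA2", "LMO2", "TAL1"))
  # path s1 - s2 - s3 - s4
  net <- toy_network(c("s1", "s2"), c("s2", "s3"), c("s3", "s4"))
  sub <- extract_subnetwork(net, meta, tf_pattern = "^GATA")
  expect_setequal(sub$nodes, c("s1", "s2", "s3"))  # s3 is a first neighbour
  expect_equal(nrow(tidy(sub)), 2)

  # neighbour closure on a path: seeds {a}
  path3 <- toy_network(c("a", "b"), c("b", "c"))
  sub_a <- extract_subnetwork(path3, nodes = "a")
  expect_setequal(sub_a$nodes, c("a", "b"))
  expect_equal(nrow(tidy(sub_a)), 1)

  # filter matching everything returns the whole network
  all_sub <- extract_subnetwork(net, meta, tf_pattern = ".")
  expect_equal(tidy(all_sub), tidy(net))
  expect_setequal(all_sub$nodes, net$nodes)

  expect_warning(empty <- extract_subnetwork(net, meta,
                                             tf_pattern = "^ZZZ"),
                 "no nodes")
  expect_equal(n_nodes(empty), 0)

  # subnetwork edges are a subset of parent edges
  expect_true(all(tfnet:::pair_key(tidy(sub)$node_a, tidy(sub)$node_b) %in%
                    tfnet:::pair_key(tidy(net)$node_a, tidy(net)$node_b)))
})

test_that("metrics are invariant under node relabelling", {
  set.seed(92)
  ids <- paste0("n", 1:10)
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), 14)
  net <- tf_network(edges = tibble::tibble(node_a = pairs[pick, 1],
                                           node_b = pairs[pick, 2]),
                    nodes = ids)
  relabel <- setNames(paste0("m", sample(10)), ids)
  net2 <- tf_network(
    edges = tibble::tibble(node_a = unname(relabel[tidy(net)$node_a]),
                           node_b = unname(relabel[tidy(net)$node_b])),
    nodes = unname(relabel)
  )
  expect_equal(degree_distribution(net), degree_distribution(net2))
  expect_equal(clustering_by_degree(net), clustering_by_degree(net2))
  expect_equal(mean_neighbour_degree(net), mean_neighbour_degree(net2))
})
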