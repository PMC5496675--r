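#' Consensus network across inference algorithms
#'
#' Combines per-algorithm networks by edge voting: an edge is kept when it
#' was discovered by at least `min_support` of the input algorithms.  With
#' four algorithms and `min_support = 3` this is the construction of the
#' consensus TF association network; `min_support = 1` gives the union and
#' `min_support = length(networks)` the intersection.  The node universe is
#' preserved (isolated nodes are pruned only on export, see
#' [prune_isolated()]).
#'
#' @param networks List of [tf_network] objects over the same node
#'   universe.
#' @param min_support Minimum number of algorithms that must report an
#'   edge.
#' @return A [tf_network] whose edges carry their support count.
#' @export
consensus_network <- function(networks, min_support = 3L) {
  stopifnot(length(networks) >= 1L, all(vapply(networks, is_tf_network, TRUE)))
  if (min_support < 1L || min_support > length(networks)) {
    abort(sprintf("min_support must be in [1, %d]", length(networks)))
  }
  universe <- networks[[1]]$nodes
  for (nw in networks[-1]) {
    if (!identical(nw$nodes, universe)) {
      abort("all networks must share the same node universe")
    }
  }
  votes <- bind_rows(lapply(networks, function(nw) {
    select(nw$edges, "node_a", "node_b")
  })) |>
    count(.data$node_a, .data$node_b, name = "support")
  kept <- filter(votes, .data$support >= min_support)
  tf_network(edges = kept, nodes = universe)
}

#' Drop isolated nodes
#'
#' Removes degree-0 nodes from the node universe and reports how many were
#' removed; edges are untouched.
#'
#' @param network A [tf_network].
#' @return A list with `network` (pruned) and `n_removed`.
#' @export
prune_isolated <- function(network) {
  stopifnot(is_tf_network(network))
  deg <- node_degrees(network)
  keep <- names(deg)[deg > 0L]
  list(
    network = tf_network(edges = network$edges, nodes = keep),
    n_removed = sum(deg == 0L)
  )
}

#' Annotate network edges with a protein-interaction gold standard
#'
#' Labels an edge `string_high_confidence` when the TF pair of its two
#' endpoint samples is present in the gold standard, and additionally
#' `string_physical` when that pair is flagged as a physical interaction.
#' Edges joining two samples of the same TF are never labelled (a TF paired
#' with itself is outside the gold standard's universe of unordered pairs).
#'
#' @param network A [tf_network].
#' @param gold A [gold_standard] tibble.
#' @param metadata Metadata tibble mapping every node (`sample_id`) to a
#'   `tf_name`.
#' @return The network with edge annotations filled in.
#' @export
annotate_with_gold <- function(network, gold, metadata) {
  stopifnot(is_tf_network(network))
  tf_of <- setNames(metadata$tf_name, metadata$sample_id)
  missing_nodes <- setdiff(network$nodes, names(tf_of))
  if (length(missing_nodes)) {
    abort(sprintf("node(s) missing from metadata: %s",
                  paste(missing_nodes, collapse = ", ")))
  }
  if (!nrow(network$edges)) return(network)
  tf_a <- tf_of[network$edges$node_a]
  tf_b <- tf_of[network$edges$node_b]
  gold_keys <- pair_key(gold$tf_a, gold$tf_b)
  phys_keys <- gold_keys[gold$physical]
  keys <- pair_key(tf_a, tf_b)
  same_tf <- tf_a == tf_b
  ann <- purrr::map(seq_along(keys), function(i) {
    labels <- character()
    if (same_tf[i]) return(labels)
    if (keys[i] %in% gold_keys) labels <- c(labels, "string_high_confidence")
    if (keys[i] %in% phys_keys) labels <- c(labels, "string_physical")
    labels
  })
  edges <- mutate(network$edges, annotations = ann)
  tf_network(edges = edges, nodes = network$nodes)
}
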