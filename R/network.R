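#' Undirected sample-association networks
#'
#' `tf_network` is the package's light-weight container for an undirected,
#' unweighted graph over ChIP-seq samples: a node universe plus an edge
#' tibble.  Edges are unordered sample-id pairs stored canonically
#' (`node_a < node_b`), never self-loops; each carries a `support` count
#' (how many inference algorithms found it) and a set of annotation labels
#' (e.g. `string_high_confidence`, `string_physical`).
#'
#' @param edges A data frame with columns `node_a`, `node_b` and optionally
#'   `support` (integer, default 1) and `annotations` (list of character
#'   vectors).  May be `NULL` for an edgeless network.
#' @param nodes Character vector of node ids; defaults to (and always
#'   includes) all edge endpoints.
#' @return An object of class `tf_network`.
#' @examples
#' net <- tf_network(data.frame(node_a = c("s1", "s2"), node_b = c("s2", "s3")))
#' tidy(net)
#' glance(net)
#' @export
tf_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    edges <- tibble(node_a = character(), node_b = character(),
                    support = integer(), annotations = list())
  } else {
    edges <- as_tibble(edges)
    stopifnot(all(c("node_a", "node_b") %in% names(edges)))
    if (!"support" %in% names(edges)) edges$support <- 1L
    if (!"annotations" %in% names(edges)) {
      edges$annotations <- rep(list(character()), nrow(edges))
    }
    if (any(edges$node_a == edges$node_b)) {
      abort("self-loops are not allowed in a tf_network")
    }
    pc <- canonical_pairs(edges$node_a, edges$node_b)
    edges <- edges |>
      mutate(node_a = pc$pair_a, node_b = pc$pair_b,
             support = as.integer(.data$support)) |>
      select("node_a", "node_b", "support", "annotations")
    key <- pair_key(edges$node_a, edges$node_b)
    if (anyDuplicated(key)) {
      abort("duplicate edges in tf_network input")
    }
    edges <- arrange(edges, .data$node_a, .data$node_b)
  }
  nodes <- sort(union(as.character(nodes %||% character()),
                      c(edges$node_a, edges$node_b)))
  structure(list(nodes = nodes, edges = edges), class = "tf_network")
}

#' @rdname tf_network
#' @param x Object to test or convert.
#' @export
is_tf_network <- function(x) inherits(x, "tf_network")

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("<tf_network: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(head(tidy(x), 10))
  invisible(x)
}

#' Number of edges / nodes
#' @param network A `tf_network`.
#' @return Integer count.
#' @export
n_edges <- function(network) nrow(network$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(network) length(network$nodes)

#' Edge membership test
#'
#' @param network A `tf_network`.
#' @param a,b Node ids (vectorized).
#' @return Logical vector: is the unordered pair an edge?
#' @export
has_edge <- function(network, a, b) {
  pair_key(a, b) %in% pair_key(network$edges$node_a, network$edges$node_b)
}

#' @export
tidy.tf_network <- function(x, ...) x$edges

#' @export
glance.tf_network <- function(x, ...) {
  p <- length(x$nodes)
  deg <- node_degrees(x)
  tibble(
    nodes = p,
    edges = nrow(x$edges),
    density = if (p > 1) nrow(x$edges) / choose(p, 2) else NA_real_,
    mean_degree = if (p) mean(deg) else NA_real_,
    isolated = sum(deg == 0L)
  )
}

# Degree of every node (named integer vector over the whole universe).
node_degrees <- function(network) {
  deg <- setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$node_a, network$edges$node_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Convert between tf_network and igraph
#'
#' @param network A `tf_network`.
#' @return `as_igraph()` returns an [igraph::graph] with a `support` edge
#'   attribute; `igraph_to_tf_network()` inverts it.
#' @export
as_igraph <- function(network) {
  stopifnot(is_tf_network(network))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes),
                            name = network$nodes)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(
      g, rbind(network$edges$node_a, network$edges$node_b),
      support = network$edges$support,
      annotations = vapply(network$edges$annotations, paste, "",
                           collapse = ",")
    )
  }
  g
}

#' @rdname as_igraph
#' @param g An igraph object with named vertices.
#' @export
igraph_to_tf_network <- function(g) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) return(tf_network(nodes = nodes))
  support <- igraph::E(g)$support %||% rep(1L, nrow(el))
  ann_raw <- igraph::E(g)$annotations %||% rep("", nrow(el))
  ann <- strsplit(ifelse(is.na(ann_raw), "", ann_raw), ",", fixed = TRUE)
  tf_network(
    edges = tibble(node_a = el[, 1], node_b = el[, 2],
                   support = as.integer(support), annotations = ann),
    nodes = nodes
  )
}

#' Plot a network
#'
#' Draws the graph with a seeded Fruchterman-Reingold layout; nodes may be
#' coloured by cell type when sample metadata are supplied.
#'
#' @param object A `tf_network`.
#' @param metadata Optional metadata tibble (`sample_id`, `cell_type`) used
#'   to colour nodes.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_network <- function(object, metadata = NULL, seed = 1L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(sample_id = object$nodes, x = xy[, 1], y = xy[, 2])
  if (!is.null(metadata)) {
    nodes <- left_join(nodes, select(metadata, "sample_id", "cell_type"),
                       by = "sample_id")
  } else {
    nodes$cell_type <- NA_character_
  }
  seg <- tidy(object) |>
    left_join(setNames(nodes[c("sample_id", "x", "y")],
                       c("node_a", "xa", "ya")), by = "node_a") |>
    left_join(setNames(nodes[c("sample_id", "x", "y")],
                       c("node_b", "xb", "yb")), by = "node_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$cell_type),
      size = 2
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "cell type")
}
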