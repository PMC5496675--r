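#' Degree distribution
#'
#' Histogram of node degrees over the whole node universe, including
#' isolated (degree 0) nodes; the counts sum to the number of nodes.
#'
#' @param network A [tf_network].
#' @return Tibble with columns `degree`, `n_nodes`, sorted by degree.
#' @export
degree_distribution <- function(network) {
  deg <- node_degrees(network)
  tibble(degree = as.integer(names(table(deg))),
         n_nodes = as.integer(table(deg)))
}

#' Mean local clustering coefficient by degree class
#'
#' The local clustering coefficient of node v is
#' `2 * triangles(v) / (deg(v) * (deg(v) - 1))`, defined as 0 for degree
#' < 2 so that degree-class averages always exist.  Averaging within each
#' degree class shows whether graph connectivity depends on the number of
#' neighbours (in a scale-free graph it typically decays with degree).
#'
#' @param network A [tf_network].
#' @return Tibble with columns `degree`, `mean_clustering`, `n_nodes`.
#' @export
clustering_by_degree <- function(network) {
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  tibble(degree = as.integer(deg), clustering = cc) |>
    group_by(.data$degree) |>
    summarise(mean_clustering = mean(.data$clustering), n_nodes = n(),
              .groups = "drop") |>
    arrange(.data$degree)
}

#' Mean neighbour degree by degree class
#'
#' For each degree class k, the average over degree-k nodes of the mean
#' degree of their neighbours.  A flat or increasing profile indicates that
#' nodes attach to nodes of similar degree (assortative mixing), in
#' contrast to the hub-avoidance typical of gene regulatory networks.
#'
#' @param network A [tf_network].
#' @return Tibble with columns `degree`, `mean_neighbour_degree`,
#'   `n_nodes`; degree-0 nodes are omitted (they have no neighbours).
#' @export
mean_neighbour_degree <- function(network) {
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  knn <- igraph::knn(g)$knn  # mean neighbour degree per node (NaN if deg 0)
  tibble(degree = as.integer(deg), knn = knn) |>
    filter(.data$degree > 0) |>
    group_by(.data$degree) |>
    summarise(mean_neighbour_degree = mean(.data$knn), n_nodes = n(),
              .groups = "drop") |>
    arrange(.data$degree)
}

#' First-neighbour cell-type profile of every node
#'
#' For each node, counts its first (distance-1) neighbours by the cell type
#' they belong to; per node the counts sum to its degree.  This is the
#' neighbourhood composition analysis that reveals whether TFs associate
#' preferentially with samples from the same or related cell types.
#'
#' @param network A [tf_network].
#' @param metadata Metadata tibble mapping every node to a `cell_type`.
#' @return Tibble with columns `sample_id`, `cell_type`, `n_neighbours`
#'   (one row per node x neighbour cell type; isolated nodes yield no
#'   rows).
#' @export
first_neighbour_profile <- function(network, metadata) {
  stopifnot(is_tf_network(network))
  missing_nodes <- setdiff(network$nodes, metadata$sample_id)
  if (length(missing_nodes)) {
    abort(sprintf("node(s) missing from metadata: %s",
                  paste(missing_nodes, collapse = ", ")))
  }
  ct_of <- setNames(metadata$cell_type, metadata$sample_id)
  e <- network$edges
  incident <- tibble(
    sample_id = c(e$node_a, e$node_b),
    neighbour = c(e$node_b, e$node_a)
  )
  incident |>
    mutate(cell_type = unname(ct_of[.data$neighbour])) |>
    count(.data$sample_id, .data$cell_type, name = "n_neighbours") |>
    arrange(.data$sample_id, .data$cell_type)
}

#' Extract the subnetwork of selected nodes and their first neighbours
#'
#' Selects seed nodes by TF-name pattern and/or cell type, closes the set
#' under first neighbours, and returns the induced subgraph -- the
#' construction behind, e.g., the subnetwork of all GATA samples and their
#' closest neighbours.
#'
#' @param network A [tf_network].
#' @param metadata Metadata tibble with `sample_id`, `tf_name`,
#'   `cell_type`.
#' @param tf_pattern Regular expression matched against `tf_name` (seeds).
#' @param cell_type Exact cell type to seed from (combined with
#'   `tf_pattern` as OR if both given).
#' @param nodes Explicit seed node ids (overrides the filters).
#' @return The induced [tf_network] on seeds plus their first neighbours.
#' @export
extract_subnetwork <- function(network, metadata = NULL, tf_pattern = NULL,
                               cell_type = NULL, nodes = NULL) {
  stopifnot(is_tf_network(network))
  seeds <- if (!is.null(nodes)) {
    intersect(nodes, network$nodes)
  } else {
    if (is.null(metadata)) abort("metadata required for filter-based seeds")
    sel <- rep(FALSE, nrow(metadata))
    if (!is.null(tf_pattern)) {
      sel <- sel | grepl(tf_pattern, metadata$tf_name)
    }
    if (!is.null(cell_type)) sel <- sel | metadata$cell_type %in% cell_type
    intersect(metadata$sample_id[sel], network$nodes)
  }
  if (!length(seeds)) {
    warn("subnetwork filter matched no nodes")
    return(tf_network())
  }
  e <- network$edges
  touch <- e$node_a %in% seeds | e$node_b %in% seeds
  keep_nodes <- union(seeds, c(e$node_a[touch], e$node_b[touch]))
  induced <- filter(e, .data$node_a %in% keep_nodes &
                      .data$node_b %in% keep_nodes)
  tf_network(edges = induced, nodes = keep_nodes)
}

#' Plot the first-neighbour cell-type composition
#'
#' @param profile Output of [first_neighbour_profile()].
#' @return A ggplot bar chart (one bar stack per node).
#' @export
plot_neighbour_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(.data$sample_id, .data$n_neighbours,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "first neighbours", fill = "cell type") +
    ggplot2::theme_minimal()
}

#' Plot a degree distribution
#'
#' @param dist Output of [degree_distribution()].
#' @return A ggplot bar chart.
#' @export
plot_degree_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(.data$degree, .data$n_nodes)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "degree", y = "nodes") +
    ggplot2::theme_minimal()
}
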