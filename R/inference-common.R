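# dependence_matrix: p x p direct-dependence scores from one algorithm.

new_dependence_matrix <- function(values, algorithm, symmetric) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(colnames(values)))
  if (symmetric) values <- (values + t(values)) / 2
  structure(list(values = values, algorithm = algorithm,
                 symmetric = symmetric),
            class = "dependence_matrix")
}

#' @rdname infer_dependence
#' @param x Object to test.
#' @export
is_dependence_matrix <- function(x) inherits(x, "dependence_matrix")

#' @export
print.dependence_matrix <- function(x, ...) {
  cat(sprintf("<dependence_matrix [%s]: %d samples, %s>\n",
              x$algorithm, ncol(x$values),
              if (x$symmetric) "symmetric" else "asymmetric"))
  invisible(x)
}

#' @export
dim.dependence_matrix <- function(x) dim(x$values)

#' @export
tidy.dependence_matrix <- function(x, ...) {
  ids <- colnames(x$values)
  idx <- if (x$symmetric) {
    which(upper.tri(x$values), arr.ind = TRUE)
  } else {
    which(row(x$values) != col(x$values), arr.ind = TRUE)
  }
  tibble(
    sample_a = ids[idx[, 1]],
    sample_b = ids[idx[, 2]],
    score = x$values[idx],
    algorithm = x$algorithm
  ) |> arrange(.data$sample_a, .data$sample_b)
}

#' Plot a dependence matrix as a heat map
#'
#' @param object A `dependence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dependence_matrix <- function(object, ...) {
  ids <- colnames(object$values)
  df <- tidyr::expand_grid(sample_a = ids, sample_b = ids) |>
    mutate(score = as.vector(t(object$values)))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_b, .data$sample_a,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("direct dependence (%s)",
                                  object$algorithm)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Symmetrize a dependence matrix
#'
#' When an algorithm reports the influence of sample A on B separately from
#' B on A, the two are averaged: the dependence of an unordered pair is the
#' mean of the two directed scores.  Symmetric input is returned unchanged.
#'
#' @param dm A `dependence_matrix`.
#' @return A symmetric `dependence_matrix`.
#' @export
symmetrize <- function(dm) {
  stopifnot(is_dependence_matrix(dm))
  if (dm$symmetric) return(dm)
  new_dependence_matrix((dm$values + t(dm$values)) / 2,
                        algorithm = dm$algorithm, symmetric = TRUE)
}

#' Threshold a dependence matrix into a network
#'
#' Applies a significance cut to a symmetric dependence matrix: entries
#' whose absolute score passes the threshold become undirected edges.
#' Alternatively an edge budget keeps the top-k pairs by absolute score
#' (ties at the cut all included), which makes algorithms with
#' incommensurable score scales comparable.  Diagonal entries (a TF's
#' influence on itself) are always ignored: self-edges never appear.
#'
#' @param dm A symmetric `dependence_matrix` (asymmetric input is
#'   symmetrized first, with a message).
#' @param threshold Absolute-score cutoff (mutually exclusive with
#'   `edge_budget`).
#' @param edge_budget Number of edges to keep by descending absolute score.
#' @return A [tf_network] over all samples.
#' @export
select_edges <- function(dm, threshold = NULL, edge_budget = NULL) {
  stopifnot(is_dependence_matrix(dm))
  if (!dm$symmetric) {
    inform("asymmetric dependence matrix: averaging directed scores")
    dm <- symmetrize(dm)
  }
  select_pairs_network(dm$values, threshold = threshold,
                       edge_budget = edge_budget, use_abs = TRUE)
}

#' Run one or all direct-dependence estimators
#'
#' Dispatches to the four estimators of conditional (direct) dependence
#' between binding profiles: [ggm_scores()] (shrinkage partial
#' correlation), [glasso_scores()] (graphical lasso), [regression_scores()]
#' (stability-selection sparse regression) and [bn_skeleton()]
#' (Bayesian-network structure learning).  Asymmetric results are
#' symmetrized by score averaging.
#'
#' @param bm A [binding_matrix].
#' @param algorithm One of `"ggm"`, `"glasso"`, `"regression"`,
#'   `"bayes_net"`, or `"all"`.
#' @param seed Seed forwarded to the stochastic estimators.
#' @param control Named list of per-algorithm options overriding the
#'   defaults of the individual functions, e.g.
#'   `list(glasso = list(rho = 0.05), regression = list(n_resample = 50))`.
#' @return A single symmetric `dependence_matrix`, or (for `"all"`) a named
#'   list of four.
#' @export
infer_dependence <- function(bm, algorithm = c("all", "ggm", "glasso",
                                               "regression", "bayes_net"),
                             seed = 1L, control = list()) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "all") {
    algs <- c("ggm", "glasso", "regression", "bayes_net")
    return(setNames(
      lapply(algs, function(a) infer_dependence(bm, a, seed, control)), algs
    ))
  }
  opts <- control[[algorithm]] %||% list()
  dm <- switch(algorithm,
    ggm = do.call(ggm_scores, c(list(bm), opts)),
    glasso = do.call(glasso_scores, c(list(bm), opts)),
    regression = do.call(regression_scores,
                         c(list(bm), list(seed = seed), opts)),
    bayes_net = do.call(bn_skeleton, c(list(bm), list(seed = seed), opts))
  )
  symmetrize(dm)
}
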