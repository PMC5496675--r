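# Shared fixture builders and independent oracles.

segments_tbl <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end))
}

# Random segments on a small genome (may overlap, duplicate, be unsorted).
random_segments <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                            max_len = 120) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(max_pos, n, replace = TRUE) - 1L
  ) |>
    dplyr::mutate(end = start + sample.int(max_len, n, replace = TRUE))
}

# Brute-force merge oracle: union-find over all O(n^2) interval pairs,
# linking two intervals iff they share >= 1 base (book-ended pairs stay
# apart), then each component spans min(start)..max(end).
occupancy_merge_oracle <- function(segments) {
  out <- lapply(split(segments, segments$chrom), function(df) {
    n <- nrow(df)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j &&
            df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
          parent[find(i)] <- find(j)
        }
      }
    }
    comp <- vapply(seq_len(n), find, 0L)
    tibble::tibble(
      chrom = df$chrom[1],
      start = as.integer(tapply(df$start, comp, min)),
      end = as.integer(tapply(df$end, comp, max))
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# Per-base coverage of an interval set (total distinct covered bases).
covered_bases_oracle <- function(segments) {
  sum(vapply(split(segments, segments$chrom), function(df) {
    covered <- logical(max(df$end))
    for (k in seq_len(nrow(df))) {
      covered[(df$start[k] + 1):df$end[k]] <- TRUE
    }
    sum(covered)
  }, 0))
}

# Naive O(p^3) agglomerative clustering oracle on distance matrix D,
# returning merge heights, for comparison with hclust.
agglom_heights_oracle <- function(D, method = "complete") {
  active <- lapply(seq_len(nrow(D)), identity)
  heights <- numeric()
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        d <- switch(method,
          complete = max(D[active[[i]], active[[j]]]),
          average = mean(D[active[[i]], active[[j]]]),
          single = min(D[active[[i]], active[[j]]])
        )
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- c(active[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}

# Partial-correlation oracle: correlation of residuals after regressing
# each of columns i, j on all the remaining columns.
residual_pcor_oracle <- function(X, i, j) {
  others <- setdiff(seq_len(ncol(X)), c(i, j))
  ri <- stats::residuals(stats::lm(X[, i] ~ X[, others]))
  rj <- stats::residuals(stats::lm(X[, j] ~ X[, others]))
  stats::cor(ri, rj)
}

# All DAGs on p nodes (p small), as logical adjacency matrices.
all_dags <- function(p) {
  arcs <- which(diag(p) == 0)
  out <- list()
  for (mask in 0:(2^length(arcs) - 1)) {
    dag <- matrix(FALSE, p, p)
    dag[arcs[bitwAnd(mask, 2^(seq_along(arcs) - 1)) > 0]] <- TRUE
    if (is_acyclic(dag)) out[[length(out) + 1]] <- dag
  }
  out
}

is_acyclic <- function(adj) {
  m <- adj
  for (k in seq_len(nrow(adj))) {
    if (any(diag(m))) return(FALSE)
    m <- (m %*% adj) > 0
  }
  TRUE
}

# BIC score of a DAG computed independently of the package internals.
dag_bic_oracle <- function(X, dag) {
  n <- nrow(X)
  total <- 0
  for (v in seq_len(ncol(X))) {
    parents <- which(dag[, v])
    if (length(parents)) {
      config <- apply(X[, parents, drop = FALSE], 1, paste, collapse = "")
    } else {
      config <- rep("", n)
    }
    ll <- 0
    for (cf in unique(config)) {
      x <- X[config == cf, v]
      for (val in c(0, 1)) {
        cnt <- sum(x == val)
        if (cnt > 0) ll <- ll + cnt * log(cnt / length(x))
      }
    }
    total <- total + ll - log(n) / 2 * 2^length(parents)
  }
  total
}

# Exhaustive search over all DAGs: best BIC score and the skeleton(s)
# attaining it (memoizes local scores; independent of package internals).
exhaustive_best_bic <- function(X, dags) {
  n <- nrow(X)
  p <- ncol(X)
  local_memo <- new.env(parent = emptyenv())
  local_score <- function(v, parents) {
    key <- paste(v, paste(parents, collapse = ","), sep = "|")
    if (!is.null(local_memo[[key]])) return(local_memo[[key]])
    if (length(parents)) {
      config <- apply(X[, parents, drop = FALSE], 1, paste, collapse = "")
    } else {
      config <- rep("", n)
    }
    ll <- 0
    for (cf in unique(config)) {
      x <- X[config == cf, v]
      for (val in c(0, 1)) {
        cnt <- sum(x == val)
        if (cnt > 0) ll <- ll + cnt * log(cnt / length(x))
      }
    }
    local_memo[[key]] <- ll - log(n) / 2 * 2^length(parents)
    local_memo[[key]]
  }
  best_score <- -Inf
  best_skels <- list()
  for (dag in dags) {
    s <- sum(vapply(seq_len(p), function(v) local_score(v, which(dag[, v])),
                    0))
    if (s > best_score + 1e-9) {
      best_score <- s
      best_skels <- list((dag | t(dag)) * 1)
    } else if (abs(s - best_score) <= 1e-9) {
      best_skels <- c(best_skels, list((dag | t(dag)) * 1))
    }
  }
  list(score = best_score, skeletons = unique(best_skels))
}

# Toy network over named nodes from a two-column edge matrix.
toy_network <- function(..., nodes = NULL) {
  pairs <- list(...)
  tf_network(
    edges = if (length(pairs)) {
      tibble::tibble(node_a = vapply(pairs, `[[`, "", 1),
                     node_b = vapply(pairs, `[[`, "", 2))
    },
    nodes = nodes
  )
}

toy_metadata <- function(ids, tfs = toupper(ids),
                         cell_types = rep("CT1", length(ids))) {
  tibble::tibble(sample_id = ids, tf_name = tfs, cell_type = cell_types)
}

# The printed confusion-count rows of the published performance table
# (method, tp, fp, tn, fn, printed precision %, printed recall %).
published_benchmark_rows <- function() {
  tibble::tribble(
    ~method,               ~tp, ~fp, ~tn,  ~fn, ~precision, ~recall,
    "correlation_graph",    14,  78, 1366,  82,      15.22,   14.58,
    "ggm",                  44, 248, 1196,  52,      15.06,   45.83,
    "glasso",               30, 166, 1278,  66,      15.31,   31.25,
    "regression",           35, 252, 1192,  61,      12.19,   36.45,
    "bayes_net",            47, 268, 1176,  49,      14.92,   48.95,
    "tf_association",       30, 131, 1313,  66,      18.63,   31.25
  )
}
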