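#' Bayesian-network skeleton by BIC hill climbing
#'
#' Learns a directed acyclic graph over the binary binding profiles by
#' greedy hill climbing (single-arc additions, deletions and reversals)
#' maximizing the decomposable BIC score for discrete variables, with
#' seeded random restarts, then discards arc directions: the undirected
#' skeleton is the dependence structure, since edge directionality is
#' ignored downstream.
#'
#' The local score of node v with parent set P is the maximized multinomial
#' log-likelihood of v given the parent configurations minus the BIC
#' penalty `log(n)/2 * 2^|P|` (one free Bernoulli parameter per
#' configuration).  The climb never decreases the network score.
#'
#' @param bm A [binding_matrix] or binary numeric matrix.
#' @param n_restarts Number of seeded random restarts in addition to the
#'   empty-graph start.
#' @param seed Seed for the restarts.
#' @param max_parents Cap on parent-set size (bounds the per-family
#'   contingency table).
#' @param p_cap Guard: refuse to hill-climb over more than this many
#'   variables.
#' @return A symmetric binary `dependence_matrix` (tag `"bayes_net"`):
#'   `values[i, j] = 1` iff the best DAG found has an arc between i and j
#'   in either direction.  The best DAG's BIC score is stored in attribute
#'   `score`; its adjacency (arcs as a logical matrix) in attribute `dag`.
#' @export
bn_skeleton <- function(bm, n_restarts = 10L, seed = 1L, max_parents = 4L,
                        p_cap = 100L) {
  X <- if (is_binding_matrix(bm)) as.matrix(bm$X) else as.matrix(bm)
  if (!all(X %in% c(0, 1))) abort("bn_skeleton requires binary (0/1) entries")
  p <- ncol(X)
  if (p > p_cap) {
    abort(sprintf("p = %d exceeds the hill-climbing cap (%d)", p, p_cap))
  }
  storage.mode(X) <- "integer"
  cache <- new.env(parent = emptyenv())
  set.seed(seed)
  best <- NULL
  for (r in 0:n_restarts) {
    start <- if (r == 0L) {
      matrix(FALSE, p, p)
    } else {
      random_dag(p, max_parents)
    }
    res <- hill_climb(X, start, max_parents, cache)
    if (is.null(best) || res$score > best$score) best <- res
  }
  skel <- (best$dag | t(best$dag)) * 1
  dimnames(skel) <- list(colnames(X), colnames(X))
  out <- new_dependence_matrix(skel, algorithm = "bayes_net",
                               symmetric = TRUE)
  attr(out, "score") <- best$score
  attr(out, "dag") <- best$dag
  out
}

# BIC local score of node v given parent set (column indices), memoized.
bn_local_score <- function(X, v, parents, cache) {
  key <- paste(v, paste(parents, collapse = ","), sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- nrow(X)
  x <- X[, v]
  if (length(parents)) {
    config <- drop(X[, parents, drop = FALSE] %*%
                     (2L^(seq_along(parents) - 1L)))
    n_config <- 2L^length(parents)
  } else {
    config <- rep(0L, n)
    n_config <- 1L
  }
  cnt <- table(factor(config, levels = 0:(n_config - 1L)), factor(x, 0:1))
  cnt <- matrix(as.numeric(cnt), ncol = 2)
  rowtot <- rowSums(cnt)
  ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0])) -
    sum(rowtot[rowtot > 0] * log(rowtot[rowtot > 0]))
  score <- ll - log(n) / 2 * n_config
  cache[[key]] <- score
  score
}

# Total BIC score of a DAG given as a logical adjacency matrix
# (dag[u, v] = TRUE means arc u -> v).
bn_total_score <- function(X, dag, cache) {
  sum(vapply(seq_len(ncol(X)), function(v) {
    bn_local_score(X, v, which(dag[, v]), cache)
  }, 0))
}

# Is there a directed path from `from` to `to`?
has_path <- function(dag, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(dag))
  frontier <- from
  while (length(frontier)) {
    seen[frontier] <- TRUE
    nxt <- which(colSums(dag[frontier, , drop = FALSE]) > 0 & !seen)
    if (to %in% nxt) return(TRUE)
    frontier <- nxt
  }
  FALSE
}

# Greedy hill climb over DAGs from a start adjacency; first-improvement-free:
# takes the best move of each sweep, stops when no move improves.
hill_climb <- function(X, dag, max_parents, cache) {
  p <- ncol(X)
  local <- vapply(seq_len(p), function(v) {
    bn_local_score(X, v, which(dag[, v]), cache)
  }, 0)
  repeat {
    best_gain <- 1e-9
    best_move <- NULL
    for (u in seq_len(p)) {
      for (v in seq_len(p)) {
        if (u == v) next
        if (!dag[u, v]) {
          # addition u -> v (skip if creates cycle or parent cap hit)
          if (dag[v, u] || sum(dag[, v]) >= max_parents) next
          if (has_path(dag, v, u)) next
          new_v <- bn_local_score(X, v, sort(c(which(dag[, v]), u)), cache)
          gain <- new_v - local[v]
          if (gain > best_gain) {
            best_gain <- gain
            best_move <- list(type = "add", u = u, v = v, new_v = new_v)
          }
        } else {
          # deletion of u -> v
          new_v <- bn_local_score(X, v, setdiff(which(dag[, v]), u), cache)
          gain <- new_v - local[v]
          if (gain > best_gain) {
            best_gain <- gain
            best_move <- list(type = "delete", u = u, v = v, new_v = new_v)
          }
          # reversal u -> v  =>  v -> u
          if (sum(dag[, u]) < max_parents) {
            dag[u, v] <- FALSE
            cyc <- has_path(dag, u, v)
            dag[u, v] <- TRUE
            if (!cyc) {
              new_v2 <- bn_local_score(X, v, setdiff(which(dag[, v]), u),
                                       cache)
              new_u <- bn_local_score(X, u, sort(c(which(dag[, u]), v)),
                                      cache)
              gain <- (new_v2 - local[v]) + (new_u - local[u])
              if (gain > best_gain) {
                best_gain <- gain
                best_move <- list(type = "reverse", u = u, v = v,
                                  new_v = new_v2, new_u = new_u)
              }
            }
          }
        }
      }
    }
    if (is.null(best_move)) break
    m <- best_move
    if (m$type == "add") {
      dag[m$u, m$v] <- TRUE
      local[m$v] <- m$new_v
    } else if (m$type == "delete") {
      dag[m$u, m$v] <- FALSE
      local[m$v] <- m$new_v
    } else {
      dag[m$u, m$v] <- FALSE
      dag[m$v, m$u] <- TRUE
      local[m$v] <- m$new_v
      local[m$u] <- m$new_u
    }
  }
  list(dag = dag, score = sum(local))
}

# Random DAG: random topological order, arcs added with probability 0.15
# respecting the order and the parent cap.
random_dag <- function(p, max_parents) {
  ord <- sample.int(p)
  dag <- matrix(FALSE, p, p)
  for (j in 2:p) {
    for (i in 1:(j - 1)) {
      if (runif(1) < 0.15 && sum(dag[, ord[j]]) < max_parents) {
        dag[ord[i], ord[j]] <- TRUE
      }
    }
  }
  dag
}
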