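#' Collapse a sample-level network to unordered TF pairs
#'
#' A TF pair {A, B} is predicted when at least one network edge joins a
#' sample of A to a sample of B, both TFs lie in the benchmark universe,
#' and A != B (edges between samples of the same TF carry no pairwise
#' information and are discarded).
#'
#' @param network A [tf_network].
#' @param metadata Metadata tibble mapping every node to a `tf_name`.
#' @param tf_universe Character vector of TF names covered by the gold
#'   standard; pairs outside it are dropped.
#' @return Tibble with columns `tf_a`, `tf_b` (canonical order), one row
#'   per predicted pair.
#' @export
collapse_to_tf_pairs <- function(network, metadata, tf_universe) {
  stopifnot(is_tf_network(network))
  tf_of <- setNames(metadata$tf_name, metadata$sample_id)
  missing_nodes <- setdiff(network$nodes, names(tf_of))
  if (length(missing_nodes)) {
    abort(sprintf("node(s) missing from metadata: %s",
                  paste(missing_nodes, collapse = ", ")))
  }
  e <- network$edges
  if (!nrow(e)) return(tibble(tf_a = character(), tf_b = character()))
  canonical_pairs(unname(tf_of[e$node_a]), unname(tf_of[e$node_b])) |>
    rename(tf_a = "pair_a", tf_b = "pair_b") |>
    filter(.data$tf_a != .data$tf_b,
           .data$tf_a %in% tf_universe, .data$tf_b %in% tf_universe) |>
    distinct() |>
    arrange(.data$tf_a, .data$tf_b)
}

#' Confusion counts and precision/recall over a TF-pair universe
#'
#' Scores a predicted TF-pair set against gold-standard positives over the
#' universe of all `choose(u, 2)` unordered pairs of the `u` benchmark
#' TFs: `tp = |pred & gold|`, `fp = |pred \ gold|`, `fn = |gold \ pred|`,
#' `tn` the rest, with `precision = 100 * tp / (tp + fp)` and
#' `recall = 100 * tp / (tp + fn)` reported as percentages.
#'
#' @param predicted Tibble (or data frame) of predicted pairs with columns
#'   `tf_a`, `tf_b`, as from [collapse_to_tf_pairs()].
#' @param gold_positive Tibble of positive pairs (`tf_a`, `tf_b`), e.g. a
#'   [gold_standard] restricted to the universe.
#' @param tf_universe Character vector of benchmark TF names.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `precision_pct`,
#'   `recall_pct`.
#' @examples
#' confusion_counts(
#'   data.frame(tf_a = "A", tf_b = "B"),
#'   data.frame(tf_a = c("A", "A"), tf_b = c("B", "C")),
#'   tf_universe = c("A", "B", "C", "D")
#' )
#' @export
confusion_counts <- function(predicted, gold_positive, tf_universe) {
  tf_universe <- unique(tf_universe)
  u <- length(tf_universe)
  pred_keys <- unique(pair_key(predicted$tf_a, predicted$tf_b))
  gold_keys <- unique(pair_key(gold_positive$tf_a, gold_positive$tf_b))
  check_universe <- function(keys, what) {
    members <- unique(unlist(strsplit(keys, "\r", fixed = TRUE)))
    bad <- setdiff(members, tf_universe)
    if (length(bad)) {
      abort(sprintf("%s pair member(s) outside the TF universe: %s", what,
                    paste(bad, collapse = ", ")))
    }
  }
  check_universe(pred_keys, "predicted")
  check_universe(gold_keys, "gold")
  total <- choose(u, 2)
  tp <- length(intersect(pred_keys, gold_keys))
  fp <- length(setdiff(pred_keys, gold_keys))
  fn <- length(setdiff(gold_keys, pred_keys))
  tn <- total - tp - fp - fn
  precision_recall(tp, fp, tn, fn)
}

#' Precision and recall from raw confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `precision_pct`,
#'   `recall_pct` (percentages; `NaN` when the denominator is 0).
#' @export
precision_recall <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  tibble(
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    precision_pct = 100 * tp / (tp + fp),
    recall_pct = 100 * tp / (tp + fn)
  )
}

#' Benchmark several networks against one gold standard
#'
#' Collapses each network to TF pairs over the gold standard's TF universe
#' and scores it; the output mirrors a precision/recall comparison table
#' (one row per method).
#'
#' @param networks Named list of [tf_network] objects.
#' @param metadata Metadata tibble (`sample_id`, `tf_name`).
#' @param gold A [gold_standard]; its TFs define the universe unless
#'   `tf_universe` is given.
#' @param tf_universe Optional explicit TF universe (e.g. all data-set TFs
#'   with any gold-standard evidence).
#' @return Tibble with columns `method`, `tp`, `fp`, `tn`, `fn`,
#'   `precision_pct`, `recall_pct`.
#' @export
benchmark_networks <- function(networks, metadata, gold,
                               tf_universe = NULL) {
  stopifnot(is.list(networks), !is.null(names(networks)))
  tf_universe <- tf_universe %||% unique(c(gold$tf_a, gold$tf_b))
  gold_in <- filter(gold, .data$tf_a %in% tf_universe &
                      .data$tf_b %in% tf_universe)
  purrr::imap(networks, function(nw, name) {
    pred <- collapse_to_tf_pairs(nw, metadata, tf_universe)
    mutate(confusion_counts(pred, gold_in, tf_universe),
           method = name, .before = 1)
  }) |> bind_rows()
}
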