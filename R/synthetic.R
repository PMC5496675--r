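#' Planted TF-interaction model for synthetic binding data
#'
#' Defines the generative model used to validate the pipeline end to end:
#' a known (planted) TF interaction graph drives the joint distribution of
#' binary binding columns through a latent Gaussian copula.  The latent
#' precision matrix has unit diagonal, `-coupling_strength` at planted
#' edges and (optionally) `-block_coupling` between samples sharing a cell
#' type, so that partial correlations are elevated exactly where edges
#' were planted -- the quantity the conditional-dependence estimators
#' target.
#'
#' @param n_tf Number of TFs (one sample per TF).
#' @param truth_edges Tibble of planted edges (`tf_a`, `tf_b`) or an
#'   integer number of random edges to plant.
#' @param n_segments Number of genomic segments (matrix rows) to draw.
#' @param coupling_strength Magnitude of the negative off-diagonal
#'   precision entries at planted edges.
#' @param marginal_rate Marginal binding probability of every column, in
#'   (0, 1).
#' @param cell_types Either an integer number of equal-sized cell-type
#'   blocks or a character vector (length `n_tf`) assigning each sample a
#'   cell type.
#' @param block_coupling Extra within-cell-type coupling (0 disables).
#' @param genome Tibble of (`chrom`, `length`) for peak placement.
#' @param segment_length,gap Width of, and spacing between, the tiled
#'   synthetic segments (bases).
#' @param seed Seed used for the random truth graph and the data draw.
#' @return A `planted_model` list.
#' @export
planted_model <- function(n_tf = 20L, truth_edges = 30L, n_segments = 2000L,
                          coupling_strength = 0.3, marginal_rate = 0.3,
                          cell_types = 2L, block_coupling = 0,
                          genome = NULL, segment_length = 200L, gap = 100L,
                          seed = 1L) {
  stopifnot(n_tf >= 3L, marginal_rate > 0, marginal_rate < 1,
            coupling_strength >= 0)
  tf_names <- sprintf("TF%02d", seq_len(n_tf))
  sample_names <- sprintf("S%02d_%s", seq_len(n_tf), tf_names)
  if (is.numeric(truth_edges) && length(truth_edges) == 1L) {
    n_edges <- as.integer(truth_edges)
    stopifnot(n_edges <= choose(n_tf, 2))
    set.seed(seed)
    all_pairs <- which(upper.tri(diag(n_tf)), arr.ind = TRUE)
    pick <- all_pairs[sample.int(nrow(all_pairs), n_edges), , drop = FALSE]
    truth_edges <- tibble(tf_a = tf_names[pick[, 1]],
                          tf_b = tf_names[pick[, 2]])
  }
  truth_edges <- as_tibble(truth_edges)
  pc <- canonical_pairs(truth_edges$tf_a, truth_edges$tf_b)
  if (any(pc$pair_a == pc$pair_b)) abort("truth graph must have no self-loops")
  truth_edges <- distinct(tibble(tf_a = pc$pair_a, tf_b = pc$pair_b)) |>
    arrange(.data$tf_a, .data$tf_b)
  if (length(cell_types) == 1L && is.numeric(cell_types)) {
    cell_types <- sprintf("CT%d", rep(seq_len(cell_types),
                                      length.out = n_tf) |> sort())
  }
  stopifnot(length(cell_types) == n_tf)
  if (is.null(genome)) {
    need <- n_segments * (segment_length + gap)
    genome <- tibble(chrom = c("chr1", "chr2"),
                     length = rep(ceiling(need / 2) + gap, 2))
  }
  structure(
    list(
      tf_names = tf_names, sample_names = sample_names,
      truth_edges = truth_edges, n_segments = as.integer(n_segments),
      coupling_strength = coupling_strength, marginal_rate = marginal_rate,
      cell_types = cell_types, block_coupling = block_coupling,
      genome = as_tibble(genome), segment_length = as.integer(segment_length),
      gap = as.integer(gap), seed = as.integer(seed)
    ),
    class = "planted_model"
  )
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf(
    "<planted_model: %d TFs, %d planted edges, %d segments, coupling %.2f, rate %.2f>\n",
    length(x$tf_names), nrow(x$truth_edges), x$n_segments,
    x$coupling_strength, x$marginal_rate))
  invisible(x)
}

#' Metadata tibble of a planted model
#'
#' @param model A [planted_model].
#' @return Tibble with `sample_id`, `tf_name`, `cell_type`.
#' @export
model_metadata <- function(model) {
  tibble(sample_id = model$sample_names, tf_name = model$tf_names,
         cell_type = model$cell_types)
}

#' Simulate a binary binding matrix from a planted model
#'
#' Draws `n_segments` i.i.d. latent Gaussian vectors with covariance equal
#' to the (correlation-scaled) inverse of the planted precision matrix and
#' binarizes each column at the `marginal_rate` quantile of the standard
#' normal, yielding 0/1 columns whose partial-correlation structure matches
#' the planted graph.  Segments are assigned by deterministic disjoint
#' tiling of the synthetic genome.  Rows where no sample binds are kept
#' (so every column's marginal rate is exact); they disappear when the
#' matrix round-trips through peak files, since an unbound segment is
#' never written.
#'
#' @param model A [planted_model].
#' @param scale_to_pd If the planted precision matrix is not positive
#'   definite, rescale its off-diagonal block to restore diagonal
#'   dominance (with a message) instead of failing.
#' @return A [binding_matrix]; the planted edges are in
#'   `attr(, "truth_edges")` and the latent correlation in
#'   `attr(, "latent_correlation")`.
#' @export
simulate_binding <- function(model, scale_to_pd = TRUE) {
  stopifnot(inherits(model, "planted_model"))
  p <- length(model$tf_names)
  Omega <- diag(p)
  dimnames(Omega) <- list(model$sample_names, model$sample_names)
  ia <- match(model$truth_edges$tf_a, model$tf_names)
  ib <- match(model$truth_edges$tf_b, model$tf_names)
  Omega[cbind(ia, ib)] <- Omega[cbind(ib, ia)] <- -model$coupling_strength
  if (model$block_coupling > 0) {
    same_block <- outer(model$cell_types, model$cell_types, `==`)
    extra <- same_block & Omega == 0 & !diag(p)
    Omega[extra] <- -model$block_coupling
  }
  ev_min <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-8) {
    max_row <- max(rowSums(abs(Omega)) - 1)
    if (!scale_to_pd) {
      abort(sprintf(paste0(
        "planted precision matrix is not positive definite ",
        "(min eigenvalue %.3g); lower coupling_strength (off-diagonal row ",
        "sums reach %.2f)"), ev_min, max_row))
    }
    inform(sprintf(
      "rescaling off-diagonal couplings by %.3f to restore positive definiteness",
      0.95 / max_row))
    off <- !diag(p)
    Omega[off] <- Omega[off] * 0.95 / max_row
  }
  Sigma <- stats::cov2cor(solve(Omega))
  set.seed(model$seed)
  Z <- matrix(rnorm(model$n_segments * p), model$n_segments, p) %*%
    chol(Sigma)
  X <- (Z <= qnorm(model$marginal_rate)) * 1
  colnames(X) <- model$sample_names
  # all-zero rows are kept here (the marginal rate is exact); they drop out
  # naturally when the matrix round-trips through peak files, because a
  # segment no sample binds is never written
  segments <- tile_genome(model, model$n_segments)
  bm <- new_binding_matrix(as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix"),
                           segments)
  attr(bm, "truth_edges") <- model$truth_edges
  attr(bm, "latent_correlation") <- Sigma
  bm
}

# Deterministic disjoint tiling of the synthetic genome: segment i occupies
# [offset, offset + segment_length) on the first chromosome with room.
tile_genome <- function(model, n) {
  span <- model$segment_length + model$gap
  per_chrom <- floor((model$genome$length - model$gap) / span)
  if (sum(per_chrom) < n) {
    abort(sprintf("genome too small: room for %d segments, need %d",
                  sum(per_chrom), n))
  }
  chrom_idx <- rep(seq_len(nrow(model$genome)), per_chrom)[seq_len(n)]
  within <- as.integer(stats::ave(chrom_idx, chrom_idx, FUN = seq_along))
  tibble(
    chrom = model$genome$chrom[chrom_idx],
    start = (within - 1L) * span,
    end = (within - 1L) * span + model$segment_length
  )
}

#' Write a binding matrix out as per-sample BED files plus metadata
#'
#' Emits one BED file per sample (the segments where that sample's column
#' is 1) and a metadata TSV with `sample_id`, `tf`, `cell_type`,
#' `peak_path`, i.e. exactly the inputs [build_binding_matrix()] consumes;
#' reading them back reproduces the matrix.
#'
#' @param bm A [binding_matrix].
#' @param dir Output directory (created if needed).
#' @param metadata Metadata tibble (`sample_id`, `tf_name`, `cell_type`);
#'   defaults to treating each sample id as its own TF with one cell type.
#' @return Path of the written metadata TSV, invisibly.
#' @export
matrix_to_peaks <- function(bm, dir, metadata = NULL) {
  stopifnot(is_binding_matrix(bm))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sample_ids(bm)
  if (is.null(metadata)) {
    metadata <- tibble(sample_id = ids, tf_name = toupper(ids),
                       cell_type = "CT1")
  }
  stopifnot(setequal(metadata$sample_id, ids))
  paths <- file.path(dir, paste0(ids, ".bed"))
  for (j in seq_along(ids)) {
    rows <- which(bm$X[, j] != 0)
    write_bed(bm$segments[rows, ], paths[j])
  }
  meta_out <- metadata[match(ids, metadata$sample_id), ] |>
    mutate(peak_path = paths) |>
    rename(tf = "tf_name")
  meta_path <- file.path(dir, "metadata.tsv")
  readr::write_tsv(meta_out, meta_path, progress = FALSE)
  invisible(meta_path)
}

#' Synthesize a gold standard from a truth graph
#'
#' Builds a STRING-like gold standard from the planted truth graph:
#' truth edges are dropped independently with probability `noise_fn`
#' (false negatives of the database) and non-edges added with probability
#' `noise_fp` (spurious database entries); retained pairs get combined
#' scores >= 500 so they pass the high-confidence cut.  With zero noise
#' the gold standard equals the truth, enabling known-answer benchmarking.
#'
#' @param truth_edges Tibble of planted edges (`tf_a`, `tf_b`).
#' @param tf_names All TF names of the model (the pair universe).
#' @param noise_fp Probability that a non-edge enters the gold standard.
#' @param noise_fn Probability that a truth edge is missing from it.
#' @param seed Seed for the noise draws.
#' @return A [gold_standard] tibble.
#' @export
make_gold_standard <- function(truth_edges, tf_names, noise_fp = 0,
                               noise_fn = 0, seed = 1L) {
  stopifnot(noise_fp >= 0, noise_fp < 1, noise_fn >= 0, noise_fn <= 1)
  set.seed(seed)
  truth_keys <- pair_key(truth_edges$tf_a, truth_edges$tf_b)
  keep <- runif(nrow(truth_edges)) >= noise_fn
  kept <- truth_edges[keep, ]
  all_pairs <- which(upper.tri(diag(length(tf_names))), arr.ind = TRUE)
  cand <- tibble(tf_a = pmin(tf_names[all_pairs[, 1]],
                             tf_names[all_pairs[, 2]]),
                 tf_b = pmax(tf_names[all_pairs[, 1]],
                             tf_names[all_pairs[, 2]]))
  cand <- cand[!(pair_key(cand$tf_a, cand$tf_b) %in% truth_keys), ]
  spurious <- cand[runif(nrow(cand)) < noise_fp, ]
  pairs <- bind_rows(kept, spurious)
  if (!nrow(pairs)) {
    return(gold_standard(character(), character(), integer()))
  }
  gold_standard(pairs$tf_a, pairs$tf_b,
                score = as.integer(500 + round(499 * runif(nrow(pairs)))))
}

#' Write a complete synthetic study to disk
#'
#' Runs [simulate_binding()], writes per-sample BED files and metadata via
#' [matrix_to_peaks()], a STRING-dialect interaction table derived from the
#' (optionally noisy) truth graph, and the truth graph itself for scoring.
#'
#' @param model A [planted_model].
#' @param dir Output directory.
#' @inheritParams make_gold_standard
#' @return Invisibly, a list of the written paths (`metadata`, `string`,
#'   `truth`).
#' @export
simulate_study <- function(model, dir, noise_fp = 0, noise_fn = 0) {
  bm <- simulate_binding(model)
  meta_path <- matrix_to_peaks(bm, dir, model_metadata(model))
  gold <- make_gold_standard(model$truth_edges, model$tf_names,
                             noise_fp = noise_fp, noise_fn = noise_fn,
                             seed = model$seed)
  string_path <- file.path(dir, "string_links.tsv")
  readr::write_tsv(
    tibble(protein1 = gold$tf_a, protein2 = gold$tf_b,
           combined_score = gold$score),
    string_path, progress = FALSE
  )
  truth_path <- file.path(dir, "truth_edges.tsv")
  readr::write_tsv(model$truth_edges, truth_path, progress = FALSE)
  invisible(list(metadata = meta_path, string = string_path,
                 truth = truth_path))
}

#' Edge-recovery AUC of a dependence matrix against planted edges
#'
#' Ranks all unordered sample pairs by absolute dependence score and
#' reports the probability that a planted edge outranks a non-edge
#' (rank AUC, midrank ties).
#'
#' @param dm A symmetric `dependence_matrix` over the model's samples.
#' @param model A [planted_model] (or a truth-edge tibble via
#'   `truth_edges`).
#' @param truth_edges Optional explicit truth edges (`tf_a`, `tf_b`).
#' @return AUC in `[0, 1]`.
#' @export
recovery_auc <- function(dm, model = NULL, truth_edges = NULL) {
  stopifnot(is_dependence_matrix(dm))
  if (is.null(truth_edges)) truth_edges <- model$truth_edges
  ids <- sample_ids(dm)
  tf_of <- if (!is.null(model)) {
    setNames(model$tf_names, model$sample_names)
  } else {
    setNames(ids, ids)
  }
  ut <- which(upper.tri(dm$values), arr.ind = TRUE)
  keys <- pair_key(unname(tf_of[ids[ut[, 1]]]), unname(tf_of[ids[ut[, 2]]]))
  labels <- keys %in% pair_key(truth_edges$tf_a, truth_edges$tf_b)
  rank_auc(abs(dm$values[ut]), labels)
}
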