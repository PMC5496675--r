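#' Merge overlapping genomic segments
#'
#' Collapses a set of segments to their union: two segments merge exactly
#' when their half-open intersection is non-empty, i.e. they share at least
#' one base.  Book-ended segments (`end == start`) share zero bases and are
#' kept separate.  The result is sorted by (chrom, start) and pairwise
#' disjoint.
#'
#' @param segments Tibble with `chrom`, `start`, `end` (0-based half-open);
#'   may be unsorted and contain duplicates.
#' @return Tibble of merged segments, sorted, pairwise disjoint.
#' @examples
#' merge_segments(tibble::tibble(
#'   chrom = "chr1", start = c(100, 150), end = c(200, 250)
#' ))
#' @export
merge_segments <- function(segments) {
  segments <- validate_segments(segments)
  if (!nrow(segments)) return(sort_segments(segments))
  gr <- segments_to_granges(segments)
  # min.gapwidth = 0: merge iff >= 1 bp shared; book-ended ranges stay apart
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  sort_segments(granges_to_segments(merged))
}

# --- binding_matrix class ---------------------------------------------------

new_binding_matrix <- function(X, segments) {
  stopifnot(nrow(X) == nrow(segments), !is.null(colnames(X)))
  structure(list(X = X, segments = segments), class = "binding_matrix")
}

#' @rdname build_binding_matrix
#' @param x Object to test.
#' @export
is_binding_matrix <- function(x) inherits(x, "binding_matrix")

#' @export
print.binding_matrix <- function(x, ...) {
  cat(sprintf("<binding_matrix: %d segments x %d samples, %d non-zero>\n",
              nrow(x$X), ncol(x$X), Matrix::nnzero(x$X)))
  invisible(x)
}

#' @export
dim.binding_matrix <- function(x) dim(x$X)

#' Sample ids of a tfnet object
#' @param x A `binding_matrix`, `dependence_matrix` or correlation matrix.
#' @return Character vector of sample ids (column order).
#' @export
sample_ids <- function(x) {
  if (is_binding_matrix(x)) colnames(x$X)
  else if (is_dependence_matrix(x)) colnames(x$values)
  else colnames(x)
}

#' @export
tidy.binding_matrix <- function(x, ...) {
  trip <- Matrix::summary(x$X)
  tibble(
    chrom = x$segments$chrom[trip$i],
    start = x$segments$start[trip$i],
    end = x$segments$end[trip$i],
    sample_id = colnames(x$X)[trip$j]
  ) |> arrange(.data$chrom, .data$start, .data$sample_id)
}

#' @export
glance.binding_matrix <- function(x, ...) {
  tibble(
    n_segments = nrow(x$X),
    p_samples = ncol(x$X),
    n_nonzero = Matrix::nnzero(x$X),
    fill = Matrix::nnzero(x$X) / length(x$X)
  )
}

#' Build the multi-sample binary TF-binding profile
#'
#' Constructs the n x p binary matrix X at the core of the method: rows are
#' the merged union of all samples' peaks (segments sharing >= 1 bp
#' collapsed), columns are samples, and `X[i, j] = 1` exactly when sample
#' `j` has at least one peak overlapping row segment `i`.  Every row has at
#' least one 1, because rows exist only where some sample bound.
#'
#' @param metadata Metadata tibble as returned by [read_sample_metadata()]:
#'   columns `sample_id`, `tf_name`, `cell_type` and (unless `peaks` is
#'   given) `peak_path`.
#' @param peaks Optional named list of segment tibbles, one per
#'   `sample_id`, used instead of reading `peak_path` files from disk.
#' @param subsample_rows Optional integer: keep a seeded uniform subsample
#'   of this many merged rows, for tractability of downstream estimators on
#'   very large peak unions.  Requires `seed`.
#' @param seed Seed for the row subsample.
#' @return A `binding_matrix` (sparse 0/1 matrix plus its row segments).
#' @export
build_binding_matrix <- function(metadata, peaks = NULL,
                                 subsample_rows = NULL, seed = NULL) {
  metadata <- as_tibble(metadata)
  stopifnot(all(c("sample_id", "tf_name") %in% names(metadata)))
  ids <- metadata$sample_id
  if (is.null(peaks)) {
    stopifnot("peak_path" %in% names(metadata))
    peaks <- lapply(setNames(metadata$peak_path, ids), read_bed)
  } else {
    missing_ids <- setdiff(ids, names(peaks))
    if (length(missing_ids)) {
      abort(sprintf("no peaks supplied for sample(s): %s",
                    paste(missing_ids, collapse = ", ")))
    }
    peaks <- lapply(peaks[ids], validate_segments)
  }
  all_peaks <- bind_rows(peaks)
  if (!nrow(all_peaks)) abort("no peaks: the union of all samples is empty")
  merged <- merge_segments(all_peaks)
  if (!is.null(subsample_rows) && subsample_rows < nrow(merged)) {
    if (is.null(seed)) abort("row subsampling requires an explicit `seed`")
    set.seed(seed)
    keep <- sort(sample.int(nrow(merged), subsample_rows))
    merged <- merged[keep, ]
  }
  merged_gr <- segments_to_granges(merged)
  hits <- purrr::imap(peaks, function(pk, id) {
    if (!nrow(pk)) return(integer())
    ov <- GenomicRanges::findOverlaps(segments_to_granges(pk), merged_gr,
                                      minoverlap = 1L)
    unique(S4Vectors::subjectHits(ov))
  })
  i <- unlist(hits, use.names = FALSE)
  j <- rep(seq_along(ids), lengths(hits))
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(nrow(merged), length(ids)),
                            dimnames = list(NULL, ids))
  if (is.null(subsample_rows)) {
    stopifnot(all(Matrix::rowSums(X) >= 1))
  } else {
    keep_rows <- Matrix::rowSums(X) >= 1
    X <- X[keep_rows, , drop = FALSE]
    merged <- merged[keep_rows, ]
  }
  new_binding_matrix(X, merged)
}

#' Pairwise Pearson correlation of binding profiles
#'
#' Computes the p x p Pearson correlation matrix of the 0/1 columns of a
#' binding matrix.  For binary columns this equals the phi coefficient of
#' each pair's 2x2 contingency table.  Constant columns (all 0 or all 1)
#' have undefined correlations: their entries are set to `NA` and a warning
#' is issued.
#'
#' @param bm A [binding_matrix], or a plain numeric matrix (columns =
#'   samples).
#' @return A symmetric p x p matrix with unit diagonal and dimnames set to
#'   the sample ids.
#' @export
pearson_matrix <- function(bm) {
  X <- if (is_binding_matrix(bm)) bm$X else bm
  p <- ncol(X)
  if (p < 2) abort("need at least two samples")
  n <- nrow(X)
  m <- Matrix::colMeans(X)
  cross <- as.matrix(Matrix::crossprod(X)) / n
  covm <- (cross - tcrossprod(m)) * n / (n - 1)
  v <- diag(covm)
  constant <- v <= 0
  if (any(constant)) {
    warn(sprintf("constant column(s), correlations set to NA: %s",
                 paste(colnames(X)[constant], collapse = ", ")))
    v[constant] <- NA_real_
  }
  r <- covm / tcrossprod(sqrt(v))
  r[cbind(seq_len(p), seq_len(p))] <- ifelse(constant, NA_real_, 1)
  r <- (r + t(r)) / 2
  dimnames(r) <- list(colnames(X), colnames(X))
  r
}

#' Hierarchical clustering of samples from their correlation matrix
#'
#' Agglomerative clustering on the distance `1 - r`, mirroring the standard
#' heatmap companion analysis.
#'
#' @param C Correlation matrix from [pearson_matrix()].
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return An `hclust` object.
#' @export
cluster_samples <- function(C, linkage = "complete") {
  stopifnot(isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
  d <- as.dist(1 - C)
  hclust(d, method = linkage)
}

#' Correlation graph at a threshold or edge budget
#'
#' Builds the marginal-correlation baseline network: an edge joins two
#' samples when their Pearson correlation reaches `threshold`, or, in
#' budget mode, when the pair ranks among the `edge_budget` strongest
#' correlations (ties at the cut all included).  Columns with undefined
#' (`NA`) correlations contribute no edges.
#'
#' @param C Correlation matrix from [pearson_matrix()].
#' @param threshold Correlation cutoff (mutually exclusive with
#'   `edge_budget`).
#' @param edge_budget Number of edges to keep by descending correlation.
#' @return A [tf_network] over all samples in `C`.
#' @export
correlation_graph <- function(C, threshold = NULL, edge_budget = NULL) {
  select_pairs_network(C, threshold = threshold, edge_budget = edge_budget,
                       use_abs = FALSE)
}

# Shared threshold / budget edge selection over a symmetric score matrix.
select_pairs_network <- function(M, threshold = NULL, edge_budget = NULL,
                                 use_abs = TRUE) {
  if (is.null(threshold) == is.null(edge_budget)) {
    abort("give exactly one of `threshold` or `edge_budget`")
  }
  ids <- colnames(M)
  p <- ncol(M)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  score <- M[ut]
  if (use_abs) score <- abs(score)
  keep_ok <- !is.na(score)
  ut <- ut[keep_ok, , drop = FALSE]
  score <- score[keep_ok]
  keep <- if (!is.null(threshold)) {
    score >= threshold
  } else if (edge_budget <= 0) {
    rep(FALSE, length(score))
  } else if (edge_budget >= length(score)) {
    rep(TRUE, length(score))
  } else {
    cut <- sort(score, decreasing = TRUE)[edge_budget]
    score >= cut  # ties at the cut all included
  }
  tf_network(
    edges = if (any(keep)) {
      tibble(node_a = ids[ut[keep, 1]], node_b = ids[ut[keep, 2]])
    } else {
      NULL
    },
    nodes = ids
  )
}
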