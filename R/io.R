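#' Read a BED3+ peak file
#'
#' Reads genomic segments from a BED file (tab-separated, at least three
#' columns).  Coordinates follow the BED convention: 0-based, half-open
#' `[start, end)`.  `track`, `browser` and `#` comment lines are skipped;
#' columns beyond the third are ignored.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, one row per
#'   segment, in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t150\t250"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  is_data <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(is_data)
  if (!length(idx)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("line %d: expected >= 3 tab-separated fields, got %d",
                  idx[which(nf < 3L)[1]], nf[which(nf < 3L)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("line %d: non-integer coordinates", idx[bad[1]]))
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    abort(sprintf("line %d: invalid interval [%d, %d) (need 0 <= start < end)",
                  idx[bad[1]], start[bad[1]], end[bad[1]]))
  }
  tibble(chrom = chrom, start = start, end = end)
}

#' Write segments as a BED3 file
#'
#' @param segments Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  segments <- validate_segments(segments)
  readr::write_tsv(segments, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' The metadata table is a TSV with header columns `sample_id`, `tf`,
#' `cell_type` and `peak_path`; one row per ChIP-seq sample.  TF names are
#' uppercased on ingest so that name variants (e.g. "Gata2"/"GATA2") unify
#' when matched against a protein-interaction gold standard.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id`, `tf_name`, `cell_type`,
#'   `peak_path`.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "tf", "cell_type", "peak_path")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("metadata is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  meta <- meta |>
    select(dplyr::all_of(need)) |>
    rename(tf_name = "tf") |>
    mutate(dplyr::across(dplyr::everything(), as.character))
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) {
    abort(sprintf("duplicated sample_id: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(meta$tf_name) | !nzchar(trimws(meta$tf_name)))) {
    abort("every sample must have a non-empty tf name")
  }
  mutate(meta, tf_name = toupper(.data$tf_name))
}

#' Read a STRING-format protein interaction table as a gold standard
#'
#' Parses a whitespace- or tab-separated table with columns `protein1`,
#' `protein2`, `combined_score` (integer, 0-999) and optionally `action`.
#' Pairs are canonicalized as unordered (lexicographic member order),
#' self-pairs are dropped, and only pairs whose best combined score reaches
#' `min_score` are retained -- the conventional high-confidence cut is 500.
#' When `action_keyword` is given (e.g. `"binding"`), a pair is flagged
#' `physical` if any of its rows carries that keyword, which distinguishes
#' physical from purely functional associations.
#'
#' @param path Path to the interaction table.
#' @param min_score Minimum combined score to keep a pair (default 500).
#' @param action_keyword Optional action keyword flagging physical
#'   interactions.
#' @param name_map Optional named character vector mapping table protein
#'   identifiers to the TF names used in the sample metadata (applied after
#'   uppercasing).
#' @return A `gold_standard` tibble with columns `tf_a`, `tf_b`, `score`,
#'   `physical`.
#' @export
read_string_table <- function(path, min_score = 500, action_keyword = NULL,
                              name_map = NULL) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("interaction table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  score_num <- suppressWarnings(as.numeric(tab$combined_score))
  if (any(is.na(score_num)) || any(score_num != round(score_num))) {
    abort("combined_score must be integer-valued")
  }
  gold_standard(
    tf_a = tab$protein1,
    tf_b = tab$protein2,
    score = as.integer(score_num),
    action = if ("action" %in% names(tab)) tab$action else NULL,
    min_score = min_score,
    action_keyword = action_keyword,
    name_map = name_map
  )
}

#' Construct a gold standard of unordered TF pairs
#'
#' @param tf_a,tf_b Character vectors of interaction partners (one row per
#'   reported interaction; duplicates and reversed duplicates collapse).
#' @param score Integer combined score per row.
#' @param action Optional character vector of action keywords per row.
#' @inheritParams read_string_table
#' @return A tibble of class `gold_standard` with columns `tf_a`, `tf_b`,
#'   `score` (max over rows of the pair), `physical`.
#' @export
gold_standard <- function(tf_a, tf_b, score = 999L, action = NULL,
                          min_score = 0, action_keyword = NULL,
                          name_map = NULL) {
  tf_a <- toupper(as.character(tf_a))
  tf_b <- toupper(as.character(tf_b))
  if (!is.null(name_map)) {
    nm <- setNames(toupper(as.character(name_map)), toupper(names(name_map)))
    tf_a <- ifelse(tf_a %in% names(nm), nm[tf_a], tf_a)
    tf_b <- ifelse(tf_b %in% names(nm), nm[tf_b], tf_b)
  }
  if (!length(tf_a)) {
    out <- tibble(tf_a = character(), tf_b = character(),
                  score = integer(), physical = logical())
    class(out) <- c("gold_standard", class(out))
    return(out)
  }
  rows <- tibble(
    canonical_pairs(tf_a, tf_b),
    score = as.integer(rep_len(score, length(tf_a))),
    physical = if (is.null(action_keyword) || is.null(action)) {
      FALSE
    } else {
      !is.na(action) & action == action_keyword
    }
  )
  out <- rows |>
    filter(.data$pair_a != .data$pair_b) |>
    group_by(.data$pair_a, .data$pair_b) |>
    summarise(score = max(.data$score), physical = any(.data$physical),
              .groups = "drop") |>
    filter(.data$score >= min_score) |>
    rename(tf_a = "pair_a", tf_b = "pair_b") |>
    arrange(.data$tf_a, .data$tf_b)
  class(out) <- c("gold_standard", class(out))
  out
}

#' Write a network to disk
#'
#' The canonical on-disk form is an edge-list TSV with columns `node_a`,
#' `node_b`, `support_count` and `annotations` (comma-joined labels), edges
#' in lexicographic order, preceded by a `# nodes:` comment carrying the
#' full node universe so that isolated nodes survive a round trip.  GraphML
#' output (via igraph) is provided for Cytoscape import.
#'
#' @param network A [tf_network] object.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  stopifnot(is_tf_network(network))
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- tidy(network) |>
      mutate(annotations = vapply(.data$annotations, paste, "",
                                  collapse = ",")) |>
      rename(support_count = "support")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nodes: %s", paste(network$nodes, collapse = ",")),
               con)
    writeLines(paste(c("node_a", "node_b", "support_count", "annotations"),
                     collapse = "\t"), con)
    if (nrow(edges)) {
      writeLines(do.call(paste, c(as.list(edges), sep = "\t")), con)
    }
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to an edge-list TSV or GraphML file.
#' @param format `"tsv"` or `"graphml"`.
#' @return A [tf_network].
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph_to_tf_network(igraph::read_graph(path, format = "graphml")))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  nodes <- character()
  node_line <- grep("^# nodes:", lines)
  if (length(node_line)) {
    spec <- trimws(sub("^# nodes:", "", lines[node_line[1]]))
    if (nzchar(spec)) nodes <- strsplit(spec, ",", fixed = TRUE)[[1]]
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) return(tf_network(nodes = nodes))
  tab <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           node_a = "c", node_b = "c",
                           support_count = "i", annotations = "c"
                         ))
  if (!nrow(tab)) return(tf_network(nodes = nodes))
  ann_chr <- as.character(tab$annotations)
  ann <- strsplit(ifelse(is.na(ann_chr), "", ann_chr), ",", fixed = TRUE)
  tf_network(
    edges = tibble(node_a = tab$node_a, node_b = tab$node_b,
                   support = tab$support_count, annotations = ann),
    nodes = union(nodes, c(tab$node_a, tab$node_b))
  )
}

#' Write / read a binding matrix as sparse-triplet TSV
#'
#' The matrix is stored as a triplet table (`row`, `col`, both 1-based) of
#' the non-zero entries, a segments sidecar (`<path>.rows.tsv`) and the
#' sample ids in the header.  All files are plain text.
#'
#' @param bm A [binding_matrix].
#' @param path Output path for the triplet table.
#' @return `path`, invisibly.
#' @export
write_binding_matrix <- function(bm, path) {
  stopifnot(is_binding_matrix(bm))
  trip <- Matrix::summary(bm$X)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# samples: %s", paste(sample_ids(bm), collapse = ",")),
             con)
  writeLines("row\tcol", con)
  if (nrow(trip)) {
    ord <- order(trip$i, trip$j)
    writeLines(paste(trip$i[ord], trip$j[ord], sep = "\t"), con)
  }
  readr::write_tsv(bm$segments, paste0(path, ".rows.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_binding_matrix
#' @export
read_binding_matrix <- function(path) {
  lines <- readr::read_lines(path, n_max = 1L, progress = FALSE)
  if (!grepl("^# samples:", lines[1])) {
    abort("missing '# samples:' header line")
  }
  samples <- strsplit(trimws(sub("^# samples:", "", lines[1])), ",",
                      fixed = TRUE)[[1]]
  trip <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  segments <- readr::read_tsv(paste0(path, ".rows.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  X <- Matrix::sparseMatrix(i = trip$row, j = trip$col, x = 1,
                            dims = c(nrow(segments), length(samples)),
                            dimnames = list(NULL, samples))
  new_binding_matrix(X, as_tibble(segments))
}

#' Write / read a dependence matrix as dense TSV
#'
#' @param dm A [dependence_matrix].
#' @param path Output path; the algorithm tag and symmetry flag are stored
#'   in comment header lines.
#' @return `path`, invisibly.
#' @export
write_dependence_matrix <- function(dm, path) {
  stopifnot(is_dependence_matrix(dm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# algorithm: %s", dm$algorithm),
               sprintf("# symmetric: %s", dm$symmetric)), con)
  writeLines(paste(c("sample_id", sample_ids(dm)), collapse = "\t"), con)
  vals <- format(dm$values, digits = 17, trim = TRUE, scientific = FALSE)
  writeLines(paste(sample_ids(dm),
                   apply(vals, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_dependence_matrix
#' @export
read_dependence_matrix <- function(path) {
  hdr <- readr::read_lines(path, n_max = 2L, progress = FALSE)
  algorithm <- trimws(sub("^# algorithm:", "", hdr[1]))
  symmetric <- as.logical(trimws(sub("^# symmetric:", "", hdr[2])))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  values <- as.matrix(tab[-1])
  rownames(values) <- colnames(values) <- tab$sample_id
  new_dependence_matrix(values, algorithm = algorithm, symmetric = symmetric)
}
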