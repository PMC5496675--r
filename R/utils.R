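# Shared internal helpers.

# Canonicalize unordered name pairs: a < b lexicographically, self-pairs kept
# or dropped by the caller.
canonical_pairs <- function(a, b) {
  tibble(pair_a = pmin(a, b), pair_b = pmax(a, b))
}

# Deterministic pair key used for set operations on unordered pairs.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Rank-based AUC of `scores` for separating positives (labels TRUE) from
# negatives; ties get the midrank convention (Mann-Whitney).
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC undefined: need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Validate a segments tibble (chrom/start/end, 0-based half-open).
validate_segments <- function(segments, arg = "segments") {
  if (!is.data.frame(segments)) {
    abort(sprintf("`%s` must be a data frame of genomic segments", arg))
  }
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(segments))
  if (length(missing_cols)) {
    abort(sprintf("`%s` is missing column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(segments$start < 0)) abort("segment starts must be non-negative")
  if (any(segments$start >= segments$end)) {
    bad <- which(segments$start >= segments$end)[1]
    abort(sprintf("segment %d has start >= end (%d >= %d)",
                  bad, segments$start[bad], segments$end[bad]))
  }
  as_tibble(segments[need])
}

# Segments tibble (0-based half-open) -> GRanges (1-based closed).
segments_to_granges <- function(segments) {
  GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1L, end = segments$end)
  )
}

# GRanges (1-based closed) -> segments tibble (0-based half-open).
granges_to_segments <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Sort segments by (chrom, start, end).
sort_segments <- function(segments) {
  arrange(segments, .data$chrom, .data$start, .data$end)
}
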