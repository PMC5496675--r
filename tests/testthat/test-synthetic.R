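test_that("simulation is bit-identical under the same seed", {
  m <- planted_model(n_tf = 8, truth_edges = 10, n_segments = 500, seed = 5)
  bm1 <- simulate_binding(m)
  bm2 <- simulate_binding(m)
  expect_equal(as.matrix(bm1$X), as.matrix(bm2$X))
  expect_equal(bm1$segments, bm2$segments)
  m2 <- planted_model(n_tf = 8, truth_edges = 10, n_segments = 500, seed = 6)
  expect_false(identical(as.matrix(bm1$X), as.matrix(simulate_binding(m2)$X)))
})

test_that("zero coupling gives near-independent columns", {
  m <- planted_model(n_tf = 10, truth_edges = 0L, n_segments = 5000,
                     coupling_strength = 0, seed = 7)
  bm <- simulate_binding(m)
  C <- pearson_matrix(bm)
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)
})

test_that("columns hit the requested marginal rate", {
  m <- planted_model(n_tf = 10, truth_edges = 15, n_segments = 5000,
                     marginal_rate = 0.2, seed = 8)
  bm <- simulate_binding(m)
  means <- Matrix::colMeans(bm$X)
  expect_true(all(means >= 0.17 & means <= 0.23))
})

test_that("non-positive-definite couplings error or rescale as requested", {
  m <- planted_model(n_tf = 6, truth_edges = choose(6, 2),
                     coupling_strength = 0.9, n_segments = 100, seed = 9)
  expect_error(simulate_binding(m, scale_to_pd = FALSE),
               "positive definite")
  expect_message(bm <- simulate_binding(m, scale_to_pd = TRUE), "rescal")
  expect_s3_class(bm, "binding_matrix")
})

test_that("planted pairs carry higher partial correlation than non-pairs", {
  hits <- 0L
  for (s in 1:20) {
    m <- planted_model(n_tf = 8, truth_edges = 8, n_segments = 800,
                       seed = 100 + s)
    bm <- simulate_binding(m)
    auc <- recovery_auc(ggm_scores(bm), m)
    if (auc > 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # rank statistic above chance in essentially all replicates
})

test_that("matrix_to_peaks round-trips through build_binding_matrix", {
  m <- planted_model(n_tf = 6, truth_edges = 6, n_segments = 300, seed = 10)
  bm <- simulate_binding(m)
  dir <- withr::local_tempdir()
  meta_path <- matrix_to_peaks(bm, dir, model_metadata(m))
  meta <- read_sample_metadata(meta_path)
  back <- build_binding_matrix(meta)
  # all-zero rows of the simulated matrix are never written as peaks
  bound <- Matrix::rowSums(bm$X) >= 1
  expect_equal(as.matrix(back$X)[, sample_ids(bm)],
               as.matrix(bm$X)[bound, ])
  expect_equal(back$segments, bm$segments[bound, ], ignore_attr = "row.names")

  # all-ones column: a BED with every segment
  ids <- sample_ids(bm)
  one_col <- Matrix::colSums(bm$X)
  bed <- read_bed(file.path(dir, paste0(ids[1], ".bed")))
  expect_equal(nrow(bed), as.integer(one_col[1]))
})

test_that("gold-standard noise behaves at its boundaries", {
  truth <- tibble::tibble(tf_a = c("TF01", "TF02"), tf_b = c("TF03", "TF04"))
  tfs <- sprintf("TF%02d", 1:5)
  clean <- make_gold_standard(truth, tfs, noise_fp = 0, noise_fn = 0)
  expect_equal(clean$tf_a, truth$tf_a)
  expect_equal(clean$tf_b, truth$tf_b)
  expect_true(all(clean$score >= 500))

  expect_equal(nrow(make_gold_standard(truth, tfs, noise_fn = 1, seed = 2)),
               0)

  noisy <- make_gold_standard(truth, tfs, noise_fp = 0.99, seed = 3)
  expect_gt(nrow(noisy), nrow(truth))
})

test_that("a noiseless simulated study benchmarks its own truth at 100/100", {
  m <- planted_model(n_tf = 8, truth_edges = 10, n_segments = 400, seed = 11)
  dir <- withr::local_tempdir()
  paths <- simulate_study(m, dir)
  meta <- read_sample_metadata(paths$metadata)
  gold <- read_string_table(paths$string, min_score = 500)
  truth <- readr::read_tsv(paths$truth, show_col_types = FALSE)
  # the true graph scored against the noiseless gold standard is perfect
  cc <- confusion_counts(truth, gold, unique(c(gold$tf_a, gold$tf_b)))
  expect_equal(cc$precision_pct, 100)
  expect_equal(cc$recall_pct, 100)
  expect_equal(cc$fp + cc$fn, 0L)
})
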