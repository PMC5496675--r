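#' Stability-selection regression scores
#'
#' Treats each sample in turn as a regression target and scores every other
#' sample by how reliably it is selected as a predictor across randomized
#' sparse-regression fits, the stability-selection scheme used for gene
#' regulatory network inference by lasso-path methods.  For each target,
#' `n_resample` lasso paths are fit on independent half-samples of the rows
#' with predictor columns randomly rescaled by factors drawn uniformly from
#' `[alpha_randomization, 1]`; the score of predictor j for target t is the
#' fraction of fits in which j is among the first `steps_L` predictors to
#' enter the path.  Scores are directed (j -> t), so the returned matrix is
#' asymmetric; [symmetrize()] averages the two directions.
#'
#' @param bm A [binding_matrix] or numeric matrix.
#' @param n_resample Number of randomized fits per target (even, >= 2).
#' @param steps_L Path depth: a predictor counts as selected when it is
#'   among the first `steps_L` variables to enter (must be < p).
#' @param alpha_randomization Lower bound of the random predictor rescaling
#'   (1 disables the randomization).
#' @param seed Seed for the resampling and rescaling.
#' @return An asymmetric `dependence_matrix` (tag `"regression"`) with
#'   `values[j, t]` = selection frequency of predictor j for target t, in
#'   `[0, 1]`.
#' @export
regression_scores <- function(bm, n_resample = 100L, steps_L = 5L,
                              alpha_randomization = 0.2, seed = 1L) {
  X <- if (is_binding_matrix(bm)) as.matrix(bm$X) else as.matrix(bm)
  n <- nrow(X)
  p <- ncol(X)
  ids <- colnames(X)
  stopifnot(n_resample >= 2L, n_resample %% 2L == 0L)
  if (steps_L >= p) abort("steps_L must be smaller than the number of samples")
  stopifnot(alpha_randomization > 0, alpha_randomization <= 1)
  set.seed(seed)
  half <- floor(n / 2)
  freq <- matrix(0, p, p, dimnames = list(ids, ids))
  for (t in seq_len(p)) {
    y_all <- X[, t]
    pred <- setdiff(seq_len(p), t)
    hits <- numeric(p - 1)
    for (b in seq_len(n_resample)) {
      rows <- sample.int(n, half)
      w <- runif(p - 1, alpha_randomization, 1)
      Xb <- sweep(X[rows, pred, drop = FALSE], 2, w, `*`)
      sel <- lasso_entry_order(Xb, y_all[rows], steps_L)
      hits[sel] <- hits[sel] + 1
    }
    freq[pred, t] <- hits / n_resample
  }
  new_dependence_matrix(freq, algorithm = "regression", symmetric = FALSE)
}

# Indices (into columns of Xb) of the first `steps_L` distinct variables to
# enter the lasso path, in entry order, via the glmnet lambda path.
lasso_entry_order <- function(Xb, y, steps_L) {
  if (stats::sd(y) == 0) return(integer())
  fit <- tryCatch(
    glmnet::glmnet(Xb, y, family = "gaussian", standardize = TRUE,
                   nlambda = 60, dfmax = steps_L + 2L),
    error = function(e) NULL
  )
  if (is.null(fit)) return(integer())
  beta <- fit$beta != 0
  first_nz <- apply(beta, 1, function(r) if (any(r)) which(r)[1] else Inf)
  entered <- order(first_nz)[seq_len(min(steps_L, sum(is.finite(first_nz))))]
  entered[is.finite(first_nz[entered])]
}
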