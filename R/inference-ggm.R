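#' Shrinkage partial correlations (Gaussian graphical model)
#'
#' Estimates the direct dependence of every pair of samples given all
#' others as the partial correlation derived from a shrunk correlation
#' matrix.  The binary columns are treated as numeric and standardized; the
#' sample correlation matrix R is shrunk toward the identity,
#' `R* = (1 - lambda) R + lambda I`, and with `Omega = (R*)^{-1}` the
#' partial correlation is `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`.
#'
#' When `shrinkage = "auto"` the intensity is the analytic
#' variance-minimizing value
#' `lambda* = sum_{i != j} Var(r_ij) / sum_{i != j} r_ij^2`
#' (clipped to `[0, 1]`), the Ledoit-Wolf-style estimator popularized for
#' gene-network partial correlations; it vanishes as n grows, so at large n
#' the estimate approaches the plain inverse-correlation partial
#' correlation.
#'
#' @param bm A [binding_matrix] or plain numeric matrix (columns =
#'   variables), p >= 3 columns.
#' @param shrinkage `"auto"` for the analytic intensity, or a number in
#'   `[0, 1]`.
#' @return A symmetric `dependence_matrix` (tag `"ggm"`) of partial
#'   correlations with zero diagonal; the intensity used is stored in
#'   attribute `lambda`.
#' @export
ggm_scores <- function(bm, shrinkage = "auto") {
  X <- if (is_binding_matrix(bm)) as.matrix(bm$X) else as.matrix(bm)
  p <- ncol(X)
  n <- nrow(X)
  if (p < 3) abort("need at least three columns for partial correlations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("constant column(s): %s",
                  paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  Z <- scale(X)
  R <- crossprod(Z) / (n - 1)
  lambda <- if (identical(shrinkage, "auto")) {
    shrinkage_intensity(Z, R)
  } else {
    stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
    shrinkage
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  Omega <- tryCatch(solve(Rs), error = function(e) {
    abort(paste0("shrunk correlation matrix is singular; ",
                 "use shrinkage > 0 (lambda was ", signif(lambda, 3), ")"))
  })
  d <- 1 / sqrt(diag(Omega))
  pcor <- -Omega * tcrossprod(d)
  diag(pcor) <- 0
  dimnames(pcor) <- dimnames(R)
  out <- new_dependence_matrix(pcor, algorithm = "ggm", symmetric = TRUE)
  attr(out, "lambda") <- lambda
  out
}

# Analytic variance-minimizing shrinkage intensity toward the identity
# target: lambda* = sum_{i<j} Var-hat(r_ij) / sum_{i<j} r_ij^2, with the
# unbiased small-sample variance of each correlation coefficient estimated
# from the centred cross-product terms w_kij = z_ki z_kj:
#   Var-hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - mean_k w_kij)^2.
shrinkage_intensity <- function(Z, R) {
  n <- nrow(Z)
  wbar <- crossprod(Z) / n                  # mean_k z_ki z_kj
  w2bar <- crossprod(Z^2) / n               # mean_k (z_ki z_kj)^2
  var_r <- n^2 / (n - 1)^3 * (w2bar - wbar^2)
  off <- upper.tri(R)
  denom <- sum(R[off]^2)
  if (denom == 0) return(1)
  min(1, max(0, sum(var_r[off]) / denom))
}
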