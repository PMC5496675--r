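#' Graphical lasso: sparse precision-matrix estimation
#'
#' Maximizes the L1-penalized Gaussian log-likelihood
#' `log det(Theta) - tr(S Theta) - rho * sum_{i != j} |Theta_ij|`
#' by block coordinate descent (one row/column at a time, each block a
#' lasso problem solved by coordinate descent), the standard pathwise
#' algorithm for sparse inverse covariance.  Only off-diagonal entries are
#' penalized.  The direct-dependence score for a pair is the partial
#' correlation implied by the estimated precision matrix,
#' `-Theta_ij / sqrt(Theta_ii Theta_jj)`.
#'
#' @param S Symmetric positive semi-definite covariance or correlation
#'   matrix (with dimnames).
#' @param rho Non-negative L1 penalty on off-diagonal precision entries.
#' @param tol Convergence tolerance: the sweep stops when the maximum
#'   absolute change of any fitted covariance entry falls below
#'   `tol * mean(|S_offdiag|)`.
#' @param max_iter Maximum number of full sweeps.
#' @return A list with `theta` (precision matrix), `w` (fitted covariance),
#'   `scores` (a symmetric `dependence_matrix`, tag `"glasso"`),
#'   `n_iter`, and `objective` (the penalized log-likelihood after each
#'   sweep).
#' @export
glasso_fit <- function(S, rho, tol = 1e-6, max_iter = 200L) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), rho >= 0)
  if (max(abs(S - t(S))) > 1e-8) abort("S must be symmetric")
  p <- ncol(S)
  if (p < 2) abort("need at least two variables")
  W <- S
  diag(W) <- diag(S)  # off-diagonal-only penalty: diagonal unpenalized
  B <- matrix(0, p - 1, p)  # lasso coefficients per block
  thresh <- tol * max(mean(abs(S[upper.tri(S)])), .Machine$double.eps)
  objective <- numeric()
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    max_delta <- 0
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- lasso_cd(W11, s12, rho, beta = B[, j], tol = thresh / 10)
      B[, j] <- beta
      w12 <- drop(W11 %*% beta)
      max_delta <- max(max_delta, max(abs(W[idx, j] - w12)))
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    theta <- recover_theta(W, S, B)
    objective <- c(objective, glasso_objective(theta, S, rho))
    if (max_delta < thresh) break
    if (n_iter >= max_iter) {
      abort(sprintf(
        "graphical lasso did not converge in %d sweeps (last change %.3g)",
        max_iter, max_delta))
    }
  }
  theta <- recover_theta(W, S, B)
  dimnames(theta) <- dimnames(W) <- dimnames(S)
  d <- 1 / sqrt(diag(theta))
  pcor <- -theta * tcrossprod(d)
  diag(pcor) <- 0
  scores <- new_dependence_matrix(pcor, algorithm = "glasso",
                                  symmetric = TRUE)
  list(theta = theta, w = W, scores = scores, n_iter = n_iter,
       objective = objective)
}

# Coordinate-descent lasso for min_beta 1/2 beta' W11 beta - s12' beta
# + rho ||beta||_1 (the block subproblem of the graphical lasso).
lasso_cd <- function(W11, s12, rho, beta, tol, max_pass = 1000L) {
  q <- length(s12)
  wd <- diag(W11)
  for (pass in seq_len(max_pass)) {
    delta <- 0
    for (k in seq_len(q)) {
      resid <- s12[k] - drop(W11[k, ] %*% beta) + wd[k] * beta[k]
      new_b <- sign(resid) * max(abs(resid) - rho, 0) / wd[k]
      delta <- max(delta, abs(new_b - beta[k]))
      beta[k] <- new_b
    }
    if (delta < tol) break
  }
  beta
}

# Theta from the fitted covariance W and the block coefficients:
# theta_jj = 1 / (w_jj - w12' beta), theta_12 = -beta * theta_jj.
recover_theta <- function(W, S, B) {
  p <- ncol(W)
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- B[, j]
    t22 <- 1 / (W[j, j] - drop(W[idx, j] %*% beta))
    theta[j, j] <- t22
    theta[idx, j] <- -beta * t22
  }
  (theta + t(theta)) / 2
}

# Penalized log-likelihood (off-diagonal penalty only).
glasso_objective <- function(theta, S, rho) {
  ld <- determinant(theta, logarithm = TRUE)
  as.numeric(ld$modulus) - sum(S * theta) -
    rho * sum(abs(theta[upper.tri(theta)])) * 2
}

#' Graphical-lasso dependence scores from a binding matrix
#'
#' Convenience wrapper: standardizes the binary columns, forms their
#' correlation matrix and runs [glasso_fit()].
#'
#' @param bm A [binding_matrix] or numeric matrix.
#' @param rho L1 penalty (default 0.05).
#' @inheritParams glasso_fit
#' @return A symmetric `dependence_matrix` (tag `"glasso"`).
#' @export
glasso_scores <- function(bm, rho = 0.05, tol = 1e-6, max_iter = 200L) {
  X <- if (is_binding_matrix(bm)) as.matrix(bm$X) else as.matrix(bm)
  R <- stats::cor(X)
  if (anyNA(R)) abort("constant column(s): correlation undefined")
  glasso_fit(R, rho = rho, tol = tol, max_iter = max_iter)$scores
}
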