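# Non-negative least squares by the Lawson-Hanson active-set algorithm.
# This is the meta-learning step of the stacked ensemble, so it is
# implemented here rather than pulled in as a dependency.

#' Non-negative least squares
#'
#' Solves min ||b - A x||^2 subject to x >= 0 (Lawson-Hanson active set).
#' Finite termination; at the solution the KKT conditions hold: x >= 0,
#' gradient w = t(A) (b - A x) <= tol on the zero set, w = 0 on the
#' positive set.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol dual feasibility tolerance.
#' @return list with `x` (solution), `fitted`, `rss`.
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  stopifnot(is.matrix(A), nrow(A) == length(b))
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  max_iter <- 30L * n + 30L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      # least squares on the passive set
      fitP <- qr.coef(qr(A[, P, drop = FALSE]), b)
      fitP[is.na(fitP)] <- 0
      z[P] <- fitP
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P] <- x[P] > tol
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  fitted <- drop(A %*% x)
  list(x = x, fitted = fitted, rss = sum((b - fitted)^2))
}

#' Ensemble meta-weights from out-of-fold predictions
#'
#' Solves NNLS of the outcome on the matrix of out-of-fold probabilities and
#' normalizes the solution to a convex combination. If the NNLS solution is
#' identically zero (a degenerate meta-problem), the weight falls back to the
#' learner with the lowest cross-validated risk.
#'
#' @param Z n x L matrix of out-of-fold probabilities.
#' @param y binary outcome of length n.
#' @param cv_risk optional per-learner CV risk for the degenerate fallback
#'   (defaults to column mean squared error).
#' @return numeric weight vector alpha (>= 0, sums to 1).
#' @export
nnls_weights <- function(Z, y, cv_risk = NULL) {
  stopifnot(is.matrix(Z), nrow(Z) == length(y), ncol(Z) >= 1)
  sol <- nnls_solve(Z, as.numeric(y))
  a <- sol$x
  if (sum(a) <= 0) {
    if (is.null(cv_risk)) cv_risk <- colMeans((Z - y)^2)
    a <- numeric(ncol(Z))
    a[which.min(cv_risk)] <- 1
    return(a)
  }
  a / sum(a)
}
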