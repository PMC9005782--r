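#' Weighted Kabsch superposition
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum(w_i * ||R p_i + t - q_i||^2)` over proper rotations (det = +1), via
#' singular value decomposition of the weighted cross-covariance matrix. A
#' reflection solution is corrected by flipping the sign of the smallest
#' singular component, so chiral (mirror-image) point sets are never matched
#' by an improper transform.
#'
#' For rank-deficient covariance matrices (e.g. collinear points) the SVD
#' solution is still returned; it is a valid minimiser but no longer unique,
#' and the zero-determinant case is resolved towards the identity component.
#'
#' @param P n x 3 matrix of moving coordinates (Angstrom).
#' @param Q n x 3 matrix of fixed coordinates.
#' @param weights optional non-negative weights, length n, not all zero.
#'   Default: uniform.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (weighted: `sqrt(sum(w d^2) / sum(w))`), and `d2` (per-point
#'   squared deviations under the fitted transform).
#' @examples
#' P <- matrix(rnorm(15), 5, 3)
#' fit <- kabsch(P, P)
#' fit$rmsd # 0
#' @export
kabsch <- function(P, Q, weights = NULL) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  n <- nrow(P)
  assert_that(n >= 3, "kabsch() needs at least 3 point pairs")
  assert_that(all(dim(P) == dim(Q)) && ncol(P) == 3,
              "kabsch() needs matching n x 3 coordinate matrices")
  if (is.null(weights)) weights <- rep(1, n)
  assert_that(length(weights) == n && all(weights >= 0) && any(weights > 0),
              "kabsch() weights must be non-negative, length n, not all zero")
  sw <- sum(weights)
  pc <- colSums(P * weights) / sw
  qc <- colSums(Q * weights) / sw
  Pc <- P - matrix(pc, n, 3, byrow = TRUE)
  Qc <- Q - matrix(qc, n, 3, byrow = TRUE)
  H <- crossprod(Pc * weights, Qc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(qc - R %*% pc)
  D <- P %*% t(R) + matrix(tr, n, 3, byrow = TRUE) - Q
  d2 <- rowSums(D * D)
  list(rotation = R, translation = tr,
       rmsd = sqrt(sum(weights * d2) / sw), d2 = d2)
}

## determinant of a 3 x 3 matrix without generic dispatch
det3 <- function(M) {
  M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
    M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
    M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
}

## Iterative Gaussian-weighted Kabsch kernel on plain coordinate matrices.
## Weights start uniform; after each fit, per-atom deviations d_i are
## recomputed and the weights updated to exp(-d_i^2 / c), so invariant
## regions are up-weighted and mobile regions down-weighted. Converges when
## the weighted RMSD changes by less than `tol` between iterations.
## `c_param = Inf` reproduces the classical (uniform) Kabsch fit.
## The weighted fit is inlined (identical math to kabsch(), validated against
## it in the tests) because this loop dominates all-vs-all scans.
wkabsch_kernel <- function(P, Q, c_param = 2.0, tol = 1e-5, max_iter = 50L,
                           trace = FALSE) {
  n <- nrow(P)
  w <- rep(1, n)
  wrmsd_prev <- Inf
  converged <- FALSE
  iter <- 0L
  objective_trace <- if (trace) {
    matrix(NA_real_, max_iter, 2,
           dimnames = list(NULL, c("before_fit", "after_fit")))
  } else NULL
  d2 <- NULL
  R <- diag(3)
  tr <- numeric(3)
  for (iter in seq_len(max_iter)) {
    if (trace && !is.null(d2)) {
      ## objective at the incoming transform, under the weights about to be
      ## used for the refit: the refit may only decrease it
      objective_trace[iter, 1] <- sum(w * d2)
    }
    sw <- sum(w)
    pc <- colSums(P * w) / sw
    qc <- colSums(Q * w) / sw
    Pc <- P - rep(pc, each = n)
    Qc <- Q - rep(qc, each = n)
    H <- crossprod(Pc * w, Qc)
    sv <- svd(H)
    d <- sign(det3(tcrossprod(sv$v, sv$u)))
    if (d == 0) d <- 1
    sv$v[, 3] <- d * sv$v[, 3]
    R <- tcrossprod(sv$v, sv$u)
    tr <- qc - as.numeric(R %*% pc)
    D <- tcrossprod(Pc, R) - Qc
    d2 <- D[, 1]^2 + D[, 2]^2 + D[, 3]^2
    if (trace) objective_trace[iter, 2] <- sum(w * d2)
    wrmsd <- sqrt(sum(w * d2) / sw)
    if (wrmsd < tol || abs(wrmsd - wrmsd_prev) < tol) {
      converged <- TRUE
      wrmsd_prev <- wrmsd
      break
    }
    wrmsd_prev <- wrmsd
    if (is.finite(c_param)) {
      w <- exp(-d2 / c_param)
      w[w < 1e-12] <- 1e-12 # floor: all-zero weights are degenerate
    }
  }
  list(rotation = R, translation = tr, wrmsd = wrmsd_prev, d2 = d2,
       weights = w, iterations = iter, converged = converged,
       objective_trace = if (trace) objective_trace[seq_len(iter), , drop = FALSE])
}
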