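# Riemannian and Euclidean linear algebra on symmetric positive-definite
# (SPD) matrices. Covariance matrices of multichannel EEG live on the SPD
# manifold; all geometry below uses the affine-invariant metric
#   d(A, B) = || logm(A^{-1/2} B A^{-1/2}) ||_F ,
# the standard choice in the EEG/BCI Riemannian literature.

SYM_TOL <- 1e-10

#' Validate a symmetric positive-definite matrix
#'
#' Checks symmetry (relative to the Frobenius norm) and strict positive
#' definiteness. Optionally applies a trace-scaled ridge to rank-deficient
#' estimates so that downstream matrix logarithms and inverse square roots
#' are well defined.
#'
#' @param U square numeric matrix.
#' @param regularize if `TRUE`, add `eps * tr(U)/c` to the diagonal when the
#'   smallest eigenvalue is below that level.
#' @param eps relative ridge magnitude (default `1e-10`).
#' @return the (possibly regularized) matrix, symmetrized to machine
#'   precision.
#' @export
as_spd <- function(U, regularize = TRUE, eps = 1e-10) {
  if (!is.matrix(U) || nrow(U) != ncol(U))
    stop("invalid-covariance: not a square matrix")
  nf <- norm(U, "F")
  if (nf > 0 && norm(U - t(U), "F") / nf > SYM_TOL)
    stop("invalid-covariance: matrix is not symmetric")
  U <- (U + t(U)) / 2
  c <- nrow(U)
  ridge <- eps * sum(diag(U)) / c
  ev_min <- min(eigen(U, symmetric = TRUE, only.values = TRUE)$values)
  if (regularize && ev_min < ridge) {
    if (ridge <= 0) ridge <- eps # all-zero matrix
    U <- U + diag(ridge, c)
    ev_min <- ev_min + ridge
  }
  if (ev_min <= 0)
    stop("invalid-covariance: matrix is not positive definite")
  U
}

# eigendecomposition with ascending eigenvalues (base::eigen is descending)
eig_asc <- function(U) {
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  idx <- rev(seq_along(e$values))
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

# apply f to the eigenvalues of a symmetric matrix
spd_fun <- function(U, f) {
  e <- eig_asc(U)
  v <- e$vectors
  v %*% (f(e$values) * t(v))
}

#' Symmetric matrix square root
#'
#' Returns the unique symmetric positive-definite `M` with `M %*% M == U`,
#' the mixing matrix that maps whitened component space back to sensor
#' space.
#'
#' @param U SPD matrix.
#' @return symmetric matrix `M` with `MM^T = U`.
#' @export
sym_sqrt <- function(U) {
  U <- as_spd(U)
  spd_fun(U, sqrt)
}

sym_inv_sqrt <- function(U) spd_fun(U, function(x) 1 / sqrt(x))

logm_sym <- function(U) spd_fun(U, log)
expm_sym <- function(S) spd_fun(S, exp)

#' Affine-invariant geodesic distance between SPD matrices
#'
#' `d(A, B) = || logm(A^{-1/2} B A^{-1/2}) ||_F`. Symmetric in its
#' arguments, zero iff `A == B`, and invariant under congruence
#' `A -> W A W^T`, `B -> W B W^T` for any invertible `W`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return nonnegative scalar.
#' @export
geodesic_distance <- function(A, B) {
  if (!all(dim(A) == dim(B)))
    stop("shape error: matrices must have equal dimensions")
  A <- as_spd(A); B <- as_spd(B)
  iA <- sym_inv_sqrt(A)
  # eigenvalues of A^{-1/2} B A^{-1/2} are the generalized eigenvalues
  lam <- eigen(iA %*% B %*% iA, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}

#' Riemannian logarithmic map
#'
#' Maps an SPD matrix `P` to the tangent space at `base`:
#' `Log_base(P) = base^{1/2} logm(base^{-1/2} P base^{-1/2}) base^{1/2}`.
#' The result is a symmetric matrix; `exp_map()` inverts it.
#'
#' @param base SPD base point.
#' @param P SPD matrix to map.
#' @return symmetric tangent matrix anchored at `base`.
#' @export
log_map <- function(base, P) {
  base <- as_spd(base); P <- as_spd(P)
  if (!all(dim(base) == dim(P)))
    stop("shape error: matrices must have equal dimensions")
  hs <- sym_sqrt(base)
  ihs <- sym_inv_sqrt(base)
  S <- logm_sym(ihs %*% P %*% ihs)
  V <- hs %*% S %*% hs
  (V + t(V)) / 2
}

#' Riemannian exponential map
#'
#' Inverse of [log_map()]:
#' `Exp_base(V) = base^{1/2} expm(base^{-1/2} V base^{-1/2}) base^{1/2}`.
#'
#' @param base SPD base point.
#' @param V symmetric tangent matrix at `base`.
#' @return SPD matrix.
#' @export
exp_map <- function(base, V) {
  base <- as_spd(base)
  if (!all(dim(base) == dim(V)))
    stop("shape error: matrices must have equal dimensions")
  hs <- sym_sqrt(base)
  ihs <- sym_inv_sqrt(base)
  P <- hs %*% expm_sym(ihs %*% ((V + t(V)) / 2) %*% ihs) %*% hs
  (P + t(P)) / 2
}

#' Karcher mean (Riemannian center of mass) of SPD matrices
#'
#' The weighted Karcher mean minimizes `sum_i w_i d(C_i, U)^2` over SPD `U`
#' with `d` the affine-invariant geodesic distance. Computed by the standard
#' fixed-point iteration `U <- Exp_U( sum_i w_i Log_U(C_i) )`, initialized
#' at the weighted Euclidean mean; convergence is declared when the metric
#' norm of the tangent-space gradient falls below `tol`.
#'
#' For two matrices with equal weights this is the geodesic midpoint
#' `A^{1/2} (A^{-1/2} B A^{-1/2})^{1/2} A^{1/2}`, whose determinant is the
#' geometric mean `sqrt(det(A) det(B))` — unlike the Euclidean average,
#' whose determinant is inflated (the swelling effect).
#'
#' @param mats list of SPD matrices (all the same dimension).
#' @param weights nonnegative weights, one per matrix; normalized to sum
#'   to 1. Default: equal weights.
#' @param tol convergence tolerance on the Frobenius norm of the whitened
#'   gradient (default `1e-8`).
#' @param max_iter maximum fixed-point iterations (default 50).
#' @return SPD matrix.
#' @export
karcher_mean <- function(mats, weights = NULL, tol = 1e-8, max_iter = 50L) {
  if (!is.list(mats) || length(mats) < 1L)
    stop("karcher_mean needs at least one matrix")
  n <- length(mats)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be nonnegative, one per matrix")
  weights <- weights / sum(weights)
  mats <- lapply(mats, as_spd)
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), logical(1))))
    stop("shape error: matrices must have equal dimensions")
  if (n == 1L) return(mats[[1L]])
  if (n == 2L) {
    # exact: the weighted mean of two points lies on their geodesic,
    # A #_t B = A^{1/2} (A^{-1/2} B A^{-1/2})^t A^{1/2} with t = w_2
    if (weights[2L] == 0) return(mats[[1L]])
    if (weights[1L] == 0) return(mats[[2L]])
    hs <- sym_sqrt(mats[[1L]])
    ihs <- sym_inv_sqrt(mats[[1L]])
    W <- ihs %*% mats[[2L]] %*% ihs
    G <- hs %*% spd_fun((W + t(W)) / 2,
                        function(x) x^weights[2L]) %*% hs
    return((G + t(G)) / 2)
  }

  U <- Reduce(`+`, Map(`*`, mats, weights))
  for (it in seq_len(max_iter)) {
    hs <- sym_sqrt(U)
    ihs <- sym_inv_sqrt(U)
    # gradient in whitened coordinates, where the metric is Frobenius
    S <- matrix(0, d[1L], d[2L])
    for (i in seq_len(n)) {
      W <- ihs %*% mats[[i]] %*% ihs
      S <- S + weights[i] * logm_sym(W)
    }
    gnorm <- norm(S, "F")
    U <- hs %*% expm_sym(S) %*% hs
    U <- (U + t(U)) / 2
    if (gnorm < tol) return(U)
  }
  stop(sprintf(
    "karcher_mean failed to converge after %d iterations (gradient norm %.3e)",
    max_iter, gnorm))
}

#' Euclidean geometric (L1) median of covariance matrices
#'
#' Minimizes `sum_i || C_i - U ||_F` over `U` using the Weiszfeld
#' iteration with the Vardi-Zhang correction when an iterate lands on a
#' data point. This is the robust location estimate the ASR calibration
#' uses in place of the sample mean of windowed covariances.
#'
#' @param mats list of square matrices of equal dimension.
#' @param tol relative movement tolerance (default `1e-8`).
#' @param max_iter maximum iterations (default 100).
#' @return matrix minimizing the summed Frobenius distances.
#' @export
geometric_median_euclidean <- function(mats, tol = 1e-8, max_iter = 100L) {
  if (!is.list(mats) || length(mats) < 1L)
    stop("geometric_median_euclidean needs at least one matrix")
  n <- length(mats)
  if (n == 1L) return(mats[[1L]])
  d <- dim(mats[[1L]])
  X <- vapply(mats, as.vector, numeric(prod(d))) # p x n
  y <- rowMeans(X)
  scale <- mean(sqrt(colSums(X^2))) + .Machine$double.eps
  for (it in seq_len(max_iter)) {
    dist <- sqrt(colSums((X - y)^2))
    at_point <- dist < 1e-12 * scale
    if (any(at_point)) {
      # Vardi-Zhang: combine the Weiszfeld step over the remaining points
      # with the multiplicity of the coinciding data point
      k <- sum(at_point)
      if (k == n) break
      Xo <- X[, !at_point, drop = FALSE]
      w <- 1 / dist[!at_point]
      Ttil <- as.vector(Xo %*% w) / sum(w)
      # R = sum_{x != y} (x - y)/||x - y||; step damped by multiplicity k
      r <- sqrt(sum((as.vector(Xo %*% w) - y * sum(w))^2))
      gamma <- if (r > 0) min(1, k / r) else 1
      y_new <- (1 - gamma) * Ttil + gamma * y
    } else {
      w <- 1 / dist
      y_new <- as.vector(X %*% w) / sum(w)
    }
    if (sqrt(sum((y_new - y)^2)) <= tol * max(scale, sqrt(sum(y^2)))) {
      y <- y_new
      break
    }
    y <- y_new
  }
  matrix(y, d[1L], d[2L])
}

# objective of the Euclidean geometric median
gm_objective <- function(mats, U) {
  sum(vapply(mats, function(C) norm(C - U, "F"), numeric(1)))
}

# --- symmetric-matrix vectorization -----------------------------------------
# Off-diagonal entries scaled by sqrt(2) so the Euclidean inner product of
# the vectors equals the Frobenius inner product of the matrices.

sym_vec <- function(S) {
  c <- nrow(S)
  idx <- upper.tri(S)
  c(diag(S), sqrt(2) * S[idx])
}

sym_unvec <- function(v, c) {
  S <- matrix(0, c, c)
  diag(S) <- v[seq_len(c)]
  S[upper.tri(S)] <- v[-seq_len(c)] / sqrt(2)
  S + t(S) - diag(diag(S))
}

#' Principal geodesic analysis of SPD matrices
#'
#' Tangent-space realization of PGA: each matrix is log-mapped to the
#' tangent space at `base` (the Karcher mean by default), whitened so the
#' affine-invariant inner product becomes the Frobenius product, vectorized
#' (off-diagonals scaled by `sqrt(2)`), and the principal axes of the
#' resulting vectors extracted by an eigendecomposition of their
#' (uncentred) second-moment matrix. Variance is squared geodesic distance
#' from the base point, so the variances sum to the mean squared distance
#' of the inputs from `base`.
#'
#' @param mats list of at least two SPD matrices.
#' @param base SPD base point, or the string `"karcher"` (default) to use
#'   the Karcher mean of `mats`.
#' @return list with `directions` (list of symmetric matrices, orthonormal
#'   in the tangent metric at `base`, ordered by decreasing variance),
#'   `variances` (nonincreasing, nonnegative), `base`, and
#'   `directions_whitened` (the same directions in whitened coordinates,
#'   orthonormal under the Frobenius product).
#' @export
pga <- function(mats, base = "karcher") {
  if (!is.list(mats) || length(mats) < 2L)
    stop("insufficient data: pga needs at least two matrices")
  mats <- lapply(mats, as_spd)
  if (identical(base, "karcher")) base <- karcher_mean(mats)
  base <- as_spd(base)
  c <- nrow(base)
  ihs <- sym_inv_sqrt(base)
  hs <- sym_sqrt(base)
  n <- length(mats)
  p <- c * (c + 1L) / 2L
  Z <- matrix(0, p, n)
  for (i in seq_len(n)) {
    W <- ihs %*% mats[[i]] %*% ihs
    Z[, i] <- sym_vec(logm_sym((W + t(W)) / 2))
  }
  Mom <- Z %*% t(Z) / n
  e <- eigen(Mom, symmetric = TRUE)
  vars <- pmax(e$values, 0)
  k <- min(p, n)
  dirs_w <- lapply(seq_len(k), function(j) sym_unvec(e$vectors[, j], c))
  dirs <- lapply(dirs_w, function(G) {
    D <- hs %*% G %*% hs
    (D + t(D)) / 2
  })
  list(directions = dirs, variances = vars[seq_len(k)], base = base,
       directions_whitened = dirs_w)
}

#' Unbiased sample covariance of an EEG segment
#'
#' `U = X X^T / (t - 1)` for a channels-by-samples segment `X`, the
#' per-segment covariance estimator the Riemannian processing mode
#' decomposes once per segment. The estimate is symmetrized and, if rank
#' deficient, ridge-regularized to SPD.
#'
#' @param x an [eeg_segment()] or a channels-by-samples numeric matrix.
#' @param regularize regularize rank-deficient estimates to SPD
#'   (default `TRUE`).
#' @return c-by-c covariance matrix.
#' @export
sample_covariance_unbiased <- function(x, regularize = TRUE) {
  X <- if (inherits(x, "eeg_segment")) x$data else x
  if (!is.matrix(X)) stop("expected a channels-by-samples matrix")
  t_n <- ncol(X)
  if (t_n < 2L) stop("insufficient samples: need at least 2 samples")
  U <- tcrossprod(X) / (t_n - 1)
  U <- (U + t(U)) / 2
  if (regularize) U <- as_spd(U) else U
}
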