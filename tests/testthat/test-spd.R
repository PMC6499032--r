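# SPD manifold primitives: square roots, geodesic distance, exp/log maps,
# Karcher means, the Euclidean geometric median, and PGA.

test_that("sym_sqrt factors SPD matrices exactly", {
  expect_equal(sym_sqrt(diag(c(4, 9))), diag(c(2, 3)))
  expect_equal(sym_sqrt(diag(24)), diag(24))
  for (s in 1:20) {
    U <- rand_spd(24, seed = s)
    M <- sym_sqrt(U)
    expect_equal(M, t(M))
    expect_lt(norm(M %*% t(M) - U, "F") / norm(U, "F"), 1e-10)
  }
  expect_error(sym_sqrt(diag(c(1, -1))), "invalid-covariance")
  expect_error(sym_sqrt(matrix(1:6, 2)), "invalid-covariance")
})

test_that("geodesic distance is a congruence-invariant metric", {
  A <- rand_spd(5, seed = 1)
  expect_equal(geodesic_distance(A, A), 0, tolerance = 1e-7)
  # commuting closed form sqrt(sum(log(lambda)^2))
  expect_equal(geodesic_distance(diag(2), diag(exp(2), 2)),
               2 * sqrt(2), tolerance = 1e-10)
  for (s in 1:10) {
    A <- rand_spd(4, seed = 100 + s)
    B <- rand_spd(4, seed = 200 + s)
    d0 <- geodesic_distance(A, B)
    expect_equal(d0, geodesic_distance(B, A), tolerance = 1e-10)
    W <- rand_invertible(4, seed = 300 + s)
    expect_equal(geodesic_distance(W %*% A %*% t(W), W %*% B %*% t(W)),
                 d0, tolerance = 1e-8)
  }
  expect_error(geodesic_distance(diag(2), diag(3)), "shape")
})

test_that("exp and log maps invert each other", {
  expect_equal(log_map(diag(2), diag(exp(1), 2)), diag(2) * 1,
               tolerance = 1e-12)
  base <- rand_spd(6, seed = 3)
  expect_equal(exp_map(base, matrix(0, 6, 6)), base, tolerance = 1e-10)
  expect_equal(log_map(base, base), matrix(0, 6, 6), tolerance = 1e-8)
  for (s in 1:50) {
    base <- rand_spd(6, seed = 400 + s)
    P <- rand_spd(6, seed = 500 + s)
    Q <- exp_map(base, log_map(base, P))
    expect_lt(norm(Q - P, "F") / norm(P, "F"), 1e-8)
    expect_equal(log_map(base, P), t(log_map(base, P)), tolerance = 1e-9)
  }
})

test_that("karcher mean matches closed forms and stays congruent", {
  A <- rand_spd(4, seed = 7)
  expect_equal(karcher_mean(list(A, A)), A, tolerance = 1e-10)
  expect_equal(karcher_mean(list(diag(2), diag(4, 2))), diag(2, 2),
               tolerance = 1e-8)
  expect_equal(karcher_mean(list(diag(c(1, 4)), diag(c(4, 1)))),
               diag(2, 2), tolerance = 1e-8)
  for (s in 1:10) {
    A <- rand_spd(5, seed = 600 + s)
    B <- rand_spd(5, seed = 700 + s)
    K <- karcher_mean(list(A, B))
    hs <- sym_sqrt(A)
    ihs <- solve(hs)
    mid <- hs %*% sym_sqrt(ihs %*% B %*% ihs) %*% hs
    expect_lt(norm(K - mid, "F") / norm(mid, "F"), 1e-8)
    # determinant is the geometric mean on this manifold
    expect_equal(det(K), sqrt(det(A) * det(B)),
                 tolerance = 1e-8)
    W <- rand_invertible(5, seed = 800 + s)
    KW <- karcher_mean(list(W %*% A %*% t(W), W %*% B %*% t(W)))
    expect_lt(norm(KW - W %*% K %*% t(W), "F") / norm(KW, "F"), 1e-8)
  }
  # n > 2 path: first-order optimality of the fixed-point iterate
  mats <- lapply(1:5, function(s) rand_spd(4, seed = 900 + s))
  K <- karcher_mean(mats)
  G <- Reduce(`+`, lapply(mats, function(C) log_map(K, C))) / 5
  ihs <- solve(sym_sqrt(K))
  expect_lt(norm(ihs %*% G %*% ihs, "F"), 1e-7)
  # weighted two-point mean interpolates eigenvalues geometrically
  Kw <- karcher_mean(list(diag(c(1, 1)), diag(c(4, 4))), c(0.25, 0.75))
  expect_equal(Kw, diag(4^0.75, 2), tolerance = 1e-8)
})

test_that("Euclidean averaging swells the determinant, Karcher does not", {
  n_strict <- 0
  for (s in 1:200) {
    A <- rand_spd(4, seed = 1000 + s)
    B <- rand_spd(4, seed = 2000 + s)
    dE <- det((A + B) / 2)
    dR <- det(karcher_mean(list(A, B)))
    expect_gte(dE, dR * (1 - 1e-10))
    if (norm(A %*% B - B %*% A, "F") > 1e-8 && dE > dR * (1 + 1e-10))
      n_strict <- n_strict + 1
  }
  expect_gt(n_strict, 190) # random pairs essentially never commute
})

test_that("geometric median minimizes summed Frobenius distance", {
  A <- rand_spd(3, seed = 1)
  expect_identical(geometric_median_euclidean(list(A)), A)
  B <- rand_spd(3, seed = 2)
  expect_equal(geometric_median_euclidean(list(A, A, B)), A,
               tolerance = 1e-6)
  obj <- function(mats, U) sum(vapply(mats, function(C)
    norm(C - U, "F"), numeric(1)))
  for (s in 1:20) {
    mats <- lapply(1:5, function(i) rand_spd(3, seed = 3000 + 10 * s + i))
    med <- geometric_median_euclidean(mats)
    # independent oracle: general-purpose optimizer on the same objective
    f <- function(v) obj(mats, matrix(v, 3, 3))
    o <- optim(as.vector(Reduce(`+`, mats) / 5), f, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    expect_lt(obj(mats, med), o$value + 1e-6)
    mean_obj <- obj(mats, Reduce(`+`, mats) / length(mats))
    expect_lte(obj(mats, med), mean_obj)
  }
})

test_that("pga recovers one-dimensional geodesic families", {
  base <- rand_spd(4, seed = 5)
  set.seed(6)
  S <- matrix(rnorm(16), 4)
  S <- (S + t(S)) / 2
  mats <- lapply(seq(-1, 1, length.out = 5),
                 function(t) exp_map(base, t * S))
  pg <- pga(mats, base = base)
  expect_gte(pg$variances[1], 0.99 * sum(pg$variances))
  # all-identical inputs carry zero variance
  pg0 <- pga(list(base, base, base), base = base)
  expect_lt(sum(pg0$variances), 1e-16)
  expect_error(pga(list(base)), "insufficient")
})

test_that("pga directions are orthonormal and reconstruct the inputs", {
  base <- rand_spd(4, seed = 8)
  mats <- lapply(1:6, function(s) rand_spd(4, seed = 4000 + s))
  pg <- pga(mats, base = base)
  expect_true(all(diff(pg$variances) <= 1e-12))
  expect_true(all(pg$variances >= 0))
  # orthonormality in the affine-invariant tangent inner product at base
  ib <- solve(base)
  gram <- outer(seq_along(pg$directions), seq_along(pg$directions),
                Vectorize(function(i, j)
                  sum(diag(ib %*% pg$directions[[i]] %*%
                             ib %*% pg$directions[[j]]))))
  expect_equal(gram, diag(length(pg$directions)), tolerance = 1e-8)
  # full direction set reproduces each log-mapped input
  ihs <- solve(sym_sqrt(base))
  for (P in mats) {
    Sw <- ihs %*% log_map(base, P) %*% ihs
    coef <- vapply(pg$directions_whitened, function(G) sum(G * Sw),
                   numeric(1))
    rec <- Reduce(`+`, Map(`*`, pg$directions_whitened, coef))
    expect_lt(norm(rec - Sw, "F") / max(norm(Sw, "F"), 1e-12), 1e-8)
  }
  # variances sum to the mean squared geodesic distance from the base
  expect_equal(sum(pg$variances),
               mean(vapply(mats, function(P)
                 geodesic_distance(base, P)^2, numeric(1))),
               tolerance = 1e-8)
})

test_that("pga of a commuting diagonal family stays diagonal", {
  mats <- lapply(1:5, function(s) {
    set.seed(5000 + s)
    diag(runif(3, 0.5, 2))
  })
  pg <- pga(mats, base = diag(3))
  for (k in seq_along(pg$variances)) {
    if (pg$variances[k] > 1e-12) {
      G <- pg$directions[[k]]
      expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
    }
  }
})

test_that("unbiased sample covariance matches hand computation", {
  X <- rbind(c(1, -1, 0), c(0, 0, 0))
  expect_equal(sample_covariance_unbiased(X, regularize = FALSE),
               matrix(c(1, 0, 0, 0), 2))
  expect_equal(sample_covariance_unbiased(matrix(0, 2, 5),
                                          regularize = FALSE),
               matrix(0, 2, 2))
  expect_error(sample_covariance_unbiased(matrix(1, 3, 1)),
               "insufficient samples")
  # law of large numbers against the generating covariance
  set.seed(9)
  Sig <- rand_spd(3, seed = 10, lo = 1, hi = 3)
  L <- chol(Sig)
  X <- t(L) %*% matrix(rnorm(3 * 1e4), 3)
  U <- sample_covariance_unbiased(X)
  expect_lt(max(abs(U - Sig)) / max(abs(Sig)), 0.05)
  # regularization makes rank-deficient estimates strictly SPD
  U1 <- sample_covariance_unbiased(rbind(c(1, -1, 0), c(0, 0, 0)))
  expect_gt(min(eigen(U1, symmetric = TRUE, only.values = TRUE)$values), 0)
})
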