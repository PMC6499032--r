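# Streaming correction engines: smoothing, detection, reconstruction,
# chunked equivalence, causality, efficiency counts.

test_that("covariance smoothing follows its closed forms", {
  A <- diag(c(1, 1)); B <- diag(c(3, 3))
  expect_identical(smooth_covariance_euclidean(A, NULL, 0.7), A)
  expect_equal(smooth_covariance_euclidean(A, B, 1), A)
  expect_equal(smooth_covariance_euclidean(B, A, 0.5), diag(2, 2))
  expect_identical(smooth_covariance_riemannian(A, NULL, 0.5), A)
  expect_equal(smooth_covariance_riemannian(diag(4, 2), diag(2), 0.5),
               diag(2, 2), tolerance = 1e-8)
  # commuting diagonals interpolate geometrically per eigenvalue
  w <- 0.3
  S <- smooth_covariance_riemannian(diag(c(4, 9)), diag(c(1, 1)), w)
  expect_equal(S, diag(c(4^w, 9^w)), tolerance = 1e-8)
  # equal-weight Karcher smoothing has the geometric-mean determinant
  for (s in 1:20) {
    A <- rand_spd(4, seed = 40 + s); B <- rand_spd(4, seed = 140 + s)
    expect_equal(det(smooth_covariance_riemannian(A, B, 0.5)),
                 sqrt(det(A) * det(B)), tolerance = 1e-8)
    expect_gte(det(smooth_covariance_euclidean(A, B, 0.5)),
               det(smooth_covariance_riemannian(A, B, 0.5)) * (1 - 1e-10))
  }
  expect_error(smooth_covariance_euclidean(diag(2), diag(3), 0.5), "shape")
})

test_that("detection flags rank-one perturbations and nothing else", {
  cc <- fx_calibration("asr")
  cal <- cc$cal
  d0 <- detect_components(cal$U, cal, 1)
  expect_true(all(d0$clean_mask))
  expect_true(all(diff(d0$D) >= 0))      # ascending eigenvalues
  set.seed(44)
  v <- rnorm(24); v <- v / sqrt(sum(v^2))
  kappa <- 1e4 * max(d0$D)
  d1 <- detect_components(cal$U + kappa * tcrossprod(v), cal, 1)
  expect_equal(sum(!d1$clean_mask), 1)
  expect_false(d1$clean_mask[24])        # the largest component
  expect_gt(abs(sum(d1$V[, 24] * v)), 0.99)
  # maxdims protection keeps the smallest components
  d2 <- detect_components(1e6 * cal$U, cal, 0.25)
  expect_true(all(d2$clean_mask[1:18]))
  expect_true(d2$saturated)
})

test_that("reconstruction zeroes flagged canonical components", {
  X <- matrix(rnorm(20), 2)
  keep_all <- reconstruct(X, diag(2), diag(2), c(TRUE, TRUE))
  expect_identical(keep_all, X)          # bit-identical when all clean
  r <- reconstruct(X, diag(2), diag(2), c(TRUE, FALSE))
  expect_equal(r[2, ], rep(0, 10))
  expect_equal(r[1, ], X[1, ])
  expect_error(reconstruct(X, diag(2), diag(2), c(FALSE, FALSE)),
               "no clean subspace")
  # with V the eigenbasis of M the operator is an orthogonal projection:
  # energy can never grow
  cc <- fx_calibration("asr")
  cal <- cc$cal
  e <- rasr:::eig_asc(cal$M)
  mask <- rep(TRUE, 24); mask[24] <- FALSE
  Y <- reconstruct(cc$calseg$data[, 1:500], cal$M, e$vectors, mask)
  expect_lte(norm(Y, "F"), norm(cc$calseg$data[, 1:500], "F") * (1 + 1e-9))
})

test_that("processing state resolves the analysis-window arithmetic", {
  cc <- fx_calibration("asr")
  st <- asr_new_state(cc$cal, cc$params)
  expect_equal(st$range, 125L)           # 250 Hz x 0.5 s
  expect_equal(st$lookahead, 46L)        # (125 - 32) / 2
  str <- asr_new_state(fx_calibration("rasr")$cal,
                       fx_calibration("rasr")$params)
  expect_equal(str$range, 75L)           # 250 Hz x 0.3 s
  expect_equal(str$lookahead, 37L)       # (150 - 75) / 2
  expect_true(all(st$R_prev == diag(24)))
})

test_that("clean matched data pass through nearly unchanged", {
  cc <- fx_calibration("asr")
  p <- cc$params
  test <- remove_drifts(generate_background(24, 30, 250, 10, 1.5,
                                            seed = 45), p$hp_band)
  out <- asr_clean(test, cc$cal, p)
  expect_equal(dim(out$data), dim(test$data))
  cors <- vapply(1:24, function(i)
    cor(test$data[i, ], out$data[i, ]), numeric(1))
  expect_gt(min(cors), 0.99)
  rms_change <- abs(sqrt(rowMeans(out$data^2)) /
                      sqrt(rowMeans(test$data^2)) - 1)
  expect_lt(max(rms_change), 0.05)
  expect_lt(attr(out, "n_flagged") / attr(out, "n_decompositions"), 0.01)
})

test_that("chunked streaming equals the offline call exactly", {
  ses <- generate_session(list(task_s = 8), seed = 46)
  for (method in c("asr", "rasr")) {
    p <- asr_params(method)
    calseg <- remove_drifts(ses$calibration, p$hp_band)
    cal <- asr_calibrate(calseg, p)
    x <- remove_drifts(ses$task, p$hp_band)
    off <- asr_clean(x, cal, p)
    st <- NULL
    pieces <- list()
    for (i in 1:8) {
      seg <- rasr:::segment_slice(x, (i - 1) * 250 + 1:250)
      r <- asr_process(seg, cal, p, st)
      st <- r$state
      pieces[[i]] <- r$data$data
    }
    fl <- asr_flush(cal, p, st)
    on <- cbind(do.call(cbind, pieces), fl$data$data)
    expect_equal(ncol(on), ncol(off$data))
    expect_lt(sqrt(mean((on - off$data)^2)), 1e-6)
    # determinism: identical runs are bit-identical
    off2 <- asr_clean(x, cal, p)
    expect_identical(off$data, off2$data)
  }
})

test_that("processing is causal within the stated horizon", {
  ses <- generate_session(list(task_s = 10), seed = 47)
  p <- asr_params("asr")
  cal <- asr_calibrate(remove_drifts(ses$calibration, p$hp_band), p)
  x <- remove_drifts(ses$task, p$hp_band)
  y <- x
  tcut <- 1500L
  y$data[, (tcut + 1):ncol(y$data)] <-
    y$data[, (tcut + 1):ncol(y$data)] + 500  # large future disturbance
  out_x <- asr_clean(x, cal, p)
  out_y <- asr_clean(y, cal, p)
  horizon <- 2L * rasr:::resolve_range(250, p$window)
  idx <- seq_len(tcut - horizon)
  expect_identical(out_x$data[, idx], out_y$data[, idx])
})

test_that("riemannian mode decomposes once per segment", {
  ses <- generate_session(list(task_s = 10), seed = 48)
  # identical window for both geometries isolates the chunking factor
  p_e <- asr_params("asr", window = 0.5, stepsize = 32L)
  p_r <- asr_params("rasr", window = 0.5, stepsize = 32L)
  calseg <- remove_drifts(ses$calibration, p_e$hp_band)
  x <- remove_drifts(ses$task, p_e$hp_band)
  n_seg <- ncol(x$data) %/% 125L        # 20 full segments, no remainder
  out_e <- asr_clean(x, asr_calibrate(calseg, p_e), p_e)
  out_r <- asr_clean(x, asr_calibrate(calseg, p_r), p_r)
  expect_equal(decomposition_counter(out_r), n_seg)
  expect_equal(decomposition_counter(out_e), n_seg * ceiling(125 / 32))
  expect_lt(decomposition_counter(out_r), decomposition_counter(out_e))
})

test_that("degenerate windows hold the previous operator", {
  cc <- fx_calibration("asr")
  p <- asr_params("asr", maxdims = 1.0)  # everything removable
  set.seed(49)
  blast <- eeg_segment(1e4 * matrix(rnorm(24 * 1000), 24), 250,
                       cc$cal$labels)
  out <- asr_clean(blast, cc$cal, p)
  expect_true(all(is.finite(out$data)))
  expect_equal(dim(out$data), dim(blast$data))
})

test_that("montage mismatches are rejected", {
  cc <- fx_calibration("asr")
  wrong <- eeg_segment(matrix(rnorm(8 * 500), 8), 250)
  expect_error(asr_process(wrong, cc$cal, cc$params), "incompatible")
  wrong_rate <- eeg_segment(matrix(rnorm(24 * 500), 24), 500,
                            cc$cal$labels)
  expect_error(asr_process(wrong_rate, cc$cal, cc$params), "incompatible")
})
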