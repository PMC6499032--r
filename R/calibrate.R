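# Calibration: learn the statistical model of clean data. A robust
# covariance (Euclidean geometric median of windowed sample covariances) is
# factored into a mixing matrix M (M M^T = U); a component basis V comes
# from the eigendecomposition of M (Euclidean mode) or from principal
# geodesic analysis of the windowed covariances at base U (Riemannian
# mode); per-component amplitude statistics of the spectrally shaped
# calibration data then define the threshold operator T = diag(mu + k
# sigma) V^T.

#' Per-component amplitude statistics
#'
#' Location and scale of windowed RMS amplitudes for each component
#' (row) of a component-space activation matrix. The robust variant
#' (default) uses the median and the scaled MAD (consistent with the SD
#' under normality); the classical variant uses mean and SD.
#'
#' @param activations components-by-samples matrix.
#' @param window window length in seconds (non-overlapping windows).
#' @param srate sampling rate in Hz.
#' @param robust use median / scaled-MAD (default `TRUE`).
#' @return list with `mu` and `sigma` (both length c, `sigma > 0`).
#' @export
component_statistics <- function(activations, window, srate,
                                 robust = TRUE) {
  stopifnot(is.matrix(activations))
  n <- ncol(activations)
  wlen <- resolve_range(srate, window)
  if (n < wlen)
    stop("insufficient samples: need at least one full window")
  const <- apply(activations, 1L, function(y) all(y == y[1L]))
  if (any(const))
    stop("degenerate component: zero variance in component(s) ",
         paste(which(const), collapse = ", "))
  nw <- n %/% wlen
  idx <- seq_len(nw * wlen)
  c_n <- nrow(activations)
  mu <- numeric(c_n); sigma <- numeric(c_n)
  for (j in seq_len(c_n)) {
    sq <- matrix(activations[j, idx]^2, wlen, nw)
    rms <- sqrt(colMeans(sq))
    if (robust) {
      mu[j] <- stats::median(rms)
      sigma[j] <- stats::mad(rms)
    } else {
      mu[j] <- mean(rms)
      sigma[j] <- stats::sd(rms)
    }
  }
  # guard against exactly repeating window amplitudes (e.g. pure tones)
  sigma <- pmax(sigma, 1e-12 * (mu + 1))
  list(mu = mu, sigma = sigma)
}

#' Threshold operator
#'
#' Arranges the per-component detection limits `mu + k * sigma` as the
#' c-by-c operator `T = diag(mu + k * sigma) %*% t(V)`. Row `j` of `T`
#' has Euclidean norm `mu_j + k * sigma_j`; detection compares segment
#' eigenvalues against the squared projection of `T` onto the segment
#' eigenvectors, so every detection threshold is weakly increasing in `k`.
#'
#' @param mu,sigma per-component location and scale (`sigma > 0`).
#' @param k cutoff multiplier.
#' @param V orthonormal component basis (columns).
#' @return c-by-c threshold operator.
#' @export
threshold_operator <- function(mu, sigma, k, V) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  diag(mu + k * sigma) %*% t(V)
}

#' Calibrate an ASR / rASR model from clean data
#'
#' Learns the full statistical model: spectrally shaped calibration data
#' are cut into non-overlapping analysis windows; windowed sample
#' covariances are combined by the Euclidean geometric (L1) median into a
#' robust covariance `U`; `M = sym_sqrt(U)` is the mixing matrix; the
#' component basis `V` comes from PCA of `M` (Euclidean geometry) or from
#' principal geodesic analysis of the windowed covariances at base `U`
#' (Riemannian geometry); finally per-component windowed-RMS statistics of
#' the shaped data give the thresholds `mu + k * sigma` and the operator
#' `T`.
#'
#' @param calib an [eeg_segment()] of artifact-poor data; at least one
#'   analysis window, at least 60 s recommended.
#' @param params an [asr_params()] object.
#' @return an object of class `asr_calibration` with fields `M`, `V`, `D`,
#'   `mu`, `sigma`, `T`, `k`, `U`, `srate`, `labels`, `window`,
#'   `geometry`, `shaping` (FIR taps or `NULL`).
#' @export
asr_calibrate <- function(calib, params = asr_params("asr")) {
  stopifnot(inherits(calib, "eeg_segment"), inherits(params, "asr_params"))
  srate <- calib$srate
  range <- resolve_range(srate, params$window)
  n <- n_samples(calib)
  if (n < range)
    stop("insufficient calibration: shorter than one analysis window")
  flat <- apply(calib$data, 1L, function(ch) all(ch == ch[1L]))
  if (any(flat))
    stop("degenerate channel: flat calibration channel(s) ",
         paste(calib$labels[flat], collapse = ", "))

  shaping <- NULL
  X <- calib$data
  if (isTRUE(params$use_shaping_filter)) {
    shaping <- design_shaping_fir(srate)
    X <- shape_signal(X, shaping)$shaped
  }

  nw <- n %/% range
  covs <- lapply(seq_len(nw), function(i) {
    cols <- (i - 1L) * range + seq_len(range)
    Xi <- X[, cols, drop = FALSE]
    U <- tcrossprod(Xi) / (range - 1)
    (U + t(U)) / 2
  })
  U <- as_spd(geometric_median_euclidean(covs))
  M <- sym_sqrt(U)

  if (identical(params$geometry, "riemannian") &&
      isTRUE(params$riemannian_calibration) && nw >= 2L) {
    pg <- pga(lapply(covs, as_spd), base = U)
    if (sum(pg$variances) > 0) {
      # channel-space spread operator of the tangent cloud:
      # sum_k lambda_k G_k^2 in whitened coordinates, mapped back through
      # U^{1/2}; its eigenvectors order channel directions by how much
      # manifold variation they carry
      c_n <- nrow(U)
      Aw <- matrix(0, c_n, c_n)
      for (kk in seq_along(pg$variances)) {
        G <- pg$directions_whitened[[kk]]
        Aw <- Aw + pg$variances[kk] * (G %*% G)
      }
      hs <- sym_sqrt(U)
      A <- hs %*% Aw %*% hs
      V <- eig_asc((A + t(A)) / 2)$vectors
    } else {
      V <- eig_asc(M)$vectors
    }
    D <- diag(t(V) %*% M %*% V)
  } else {
    e <- eig_asc(M)
    V <- e$vectors
    D <- e$values
  }

  stats <- component_statistics(t(V) %*% X, params$window, srate,
                                robust = isTRUE(params$robust_stats))
  Tm <- threshold_operator(stats$mu, stats$sigma, params$cutoff, V)

  structure(list(M = M, V = V, D = D, mu = stats$mu, sigma = stats$sigma,
                 T = Tm, k = params$cutoff, U = U, srate = srate,
                 labels = calib$labels, window = params$window,
                 geometry = params$geometry, shaping = shaping),
            class = "asr_calibration")
}

#' @export
print.asr_calibration <- function(x, ...) {
  cat(sprintf(
    "<asr_calibration> %d channels @ %g Hz, geometry=%s, cutoff k=%g\n",
    length(x$labels), x$srate, x$geometry, x$k))
  invisible(x)
}

#' Serialize a calibration state to JSON
#'
#' Full-precision key-value serialization so calibrate-once /
#' process-many workflows round-trip exactly.
#'
#' @param calibration an [asr_calibrate()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "asr_calibration"))
  x <- unclass(calibration)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a calibration state saved by [save_calibration()]
#'
#' @param path JSON path.
#' @return an `asr_calibration` object.
#' @export
load_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("M", "V", "T", "U"))
    x[[f]] <- as.matrix(x[[f]])
  if (!is.null(x$shaping)) x$shaping <- as.numeric(x$shaping)
  x$labels <- as.character(x$labels)
  structure(x, class = "asr_calibration")
}

#' Calibrate on self-cleaned calibration data
#'
#' Fits a provisional model on the raw calibration stretch, cleans the
#' stretch with that model, and refits on the cleaned data — the
#' calibrate-on-cleaned-calibration workflow used with recordings whose
#' rest periods may themselves contain artifacts.
#'
#' @param calib an [eeg_segment()].
#' @param params an [asr_params()] object.
#' @return an `asr_calibration` object fitted on the cleaned data.
#' @export
asr_calibrate_cleaned <- function(calib, params = asr_params("asr")) {
  cal0 <- asr_calibrate(calib, params)
  cleaned <- asr_clean(calib, cal0, params)
  asr_calibrate(cleaned, params)
}
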