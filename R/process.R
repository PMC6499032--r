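# Streaming correction engines. Data are consumed in analysis windows
# ("segments") of range = round(srate * window) samples.
#
# Euclidean mode: one covariance per stepsize chunk, combined as a
# weighted Euclidean average over the trailing analysis window (a sliding
# one-window covariance), eigendecomposed at every chunk. Riemannian mode:
# one unbiased covariance per segment, averaged with the previous
# segment's covariance by a two-point Karcher mean, decomposed once per
# segment.
#
# Reconstruction is applied to the raw samples through a short delay queue
# (half a window in Euclidean mode, one window in Riemannian mode) so that
# the covariance estimate is centred on the samples it corrects; no output
# sample uses data more than one analysis window ahead of itself.
# Successive reconstruction operators are cross-faded with a raised-cosine
# ramp over the samples between decompositions. Components whose segment
# eigenvalues exceed the projected calibration thresholds are reprojected
# onto the clean subspace through the calibration mixing matrix.

# Moore-Penrose pseudoinverse via SVD
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' Weighted Euclidean covariance smoothing
#'
#' `weight * current + (1 - weight) * prev`; returns `current` unchanged
#' when there is no previous estimate.
#'
#' @param current current covariance estimate (SPD).
#' @param prev previous smoothed covariance, or `NULL`.
#' @param weight weight of the current estimate in `[0, 1]`.
#' @return smoothed covariance.
#' @export
smooth_covariance_euclidean <- function(current, prev, weight) {
  if (is.null(prev)) return(current)
  if (!all(dim(current) == dim(prev)))
    stop("shape error: matrices must have equal dimensions")
  weight * current + (1 - weight) * prev
}

#' Riemannian (Karcher) covariance smoothing
#'
#' Weighted two-point Karcher mean of the current and previous estimates;
#' for equal weights this is the geodesic midpoint, whose determinant is
#' the geometric mean of the two determinants (no swelling).
#'
#' @inheritParams smooth_covariance_euclidean
#' @return smoothed SPD covariance.
#' @export
smooth_covariance_riemannian <- function(current, prev, weight) {
  if (is.null(prev)) return(current)
  if (!all(dim(current) == dim(prev)))
    stop("shape error: matrices must have equal dimensions")
  if (weight >= 1) return(current)
  if (weight <= 0) return(prev)
  karcher_mean(list(prev, current), c(1 - weight, weight))
}

#' Detect artifactual components of a segment covariance
#'
#' Eigendecomposes the (smoothed) segment covariance with ascending
#' eigenvalues and flags component `j` when its eigenvalue exceeds the
#' squared projection of the calibration threshold operator,
#' `D[j] > sum_i (T V)_{ij}^2`. At most `maxdims` components (the largest
#' offenders) may be flagged; lower-variance components are always kept.
#'
#' @param cov c-by-c segment covariance.
#' @param calib an [asr_calibrate()] result.
#' @param maxdims maximum removable dimensions: fraction in (0, 1] or
#'   count (default 1, all).
#' @return list with `V` (eigenvectors, ascending), `D` (eigenvalues),
#'   `clean_mask` (logical, `TRUE` = keep), and `saturated` (`TRUE` when
#'   more components exceeded their thresholds than `maxdims` allows).
#' @export
detect_components <- function(cov, calib, maxdims = 1) {
  c_n <- length(calib$labels)
  if (!all(dim(cov) == c_n))
    stop("shape error: covariance does not match the calibration montage")
  e <- eig_asc(cov)
  thr <- colSums((calib$T %*% e$vectors)^2)
  over <- e$values > thr
  md <- resolve_maxdims(maxdims, c_n)
  protected <- seq_len(c_n) <= c_n - md
  flagged <- over & !protected
  list(V = e$vectors, D = e$values, clean_mask = !flagged,
       saturated = any(over & protected))
}

# reconstruction operator R = M (K V^T M)^+ V^T with flagged rows zeroed;
# identity when all components are clean, NULL when none are
reconstruction_operator <- function(M, V, clean_mask) {
  if (all(clean_mask)) return(diag(nrow(M)))
  if (!any(clean_mask)) return(NULL)
  A <- t(V) %*% M
  A[!clean_mask, ] <- 0
  M %*% pinv(A) %*% t(V)
}

#' Reconstruct a data segment from its clean subspace
#'
#' Applies `X_clean = M (V_clean^T M)^+ V^T X`: flagged components are
#' removed and their share of the signal re-expressed through the
#' calibration mixing matrix in the retained subspace. With every
#' component clean the data are returned bit-identical.
#'
#' @param x an [eeg_segment()] or channels-by-samples matrix.
#' @param M calibration mixing matrix.
#' @param V segment eigenvectors.
#' @param clean_mask logical vector, `TRUE` = keep component.
#' @return reconstructed object of the same type as `x`.
#' @export
reconstruct <- function(x, M, V, clean_mask) {
  X <- if (inherits(x, "eeg_segment")) x$data else x
  R <- reconstruction_operator(M, V, clean_mask)
  if (is.null(R))
    stop("all components flagged: no clean subspace to reconstruct from")
  Y <- if (all(clean_mask)) X else R %*% X
  if (inherits(x, "eeg_segment")) eeg_segment(Y, x$srate, x$labels) else Y
}

#' Initialize a processing state
#'
#' @param calib an [asr_calibrate()] result.
#' @param params an [asr_params()] object.
#' @return an `asr_state` object carrying the sliding covariance buffers,
#'   the previous reconstruction operator, the sample and delay buffers,
#'   the shaping-filter carry, and the decomposition counters.
#' @export
asr_new_state <- function(calib, params) {
  c_n <- length(calib$labels)
  range <- resolve_range(calib$srate, params$window)
  riem <- identical(params$geometry, "riemannian")
  # centre the emitted chunk on the covariance estimation span:
  # (span - chunk) / 2, with span = 2 windows (Riemannian: current +
  # previous segment) or 1 window (Euclidean sliding window), chunk =
  # one segment or one stepsize chunk respectively
  look <- if (riem) range %/% 2L
          else max(0L, (range - params$stepsize) %/% 2L)
  structure(list(
    R_prev = diag(c_n),             # identity until an artifact is seen
    prev_trivial = TRUE,
    buffer = matrix(0, c_n, 0L),    # raw samples awaiting a full segment
    delay = matrix(0, c_n, 0L),     # raw samples awaiting reconstruction
    lookahead = look,
    shaped_hist = matrix(0, c_n, 0L), # trailing shaped window (Euclidean)
    prev_seg_cov = NULL,            # previous segment covariance (Riemann)
    shape_carry = NULL,             # shaping FIR streaming state
    range = range,
    n_decompositions = 0L,
    n_flagged = 0L                  # detections where >= 1 comp flagged
  ), class = "asr_state")
}

# raised-cosine cross-fade between the previous and current reconstruction
# operators over the first `ramp` samples of a chunk (the stepsize
# overlap); the new operator applies fully from there on
crossfade_apply <- function(X, R_old, R_new, old_trivial, new_trivial,
                            ramp = ncol(X)) {
  if (old_trivial && new_trivial) return(X)
  n <- ncol(X)
  ramp <- min(ramp, n)
  blend <- c((1 - cos(pi * seq_len(ramp) / ramp)) / 2,
             rep(1, n - ramp))
  Y_new <- if (new_trivial) X else R_new %*% X
  Y_old <- if (old_trivial) X else R_old %*% X
  Y_old * rep(1 - blend, each = nrow(X)) + Y_new * rep(blend, each = nrow(X))
}

# push raw samples into the delay queue, reconstruct and emit everything
# beyond the lookahead with the current operator pair
emit_through_delay <- function(state, raw_chunk) {
  q <- cbind(state$delay, raw_chunk)
  n_emit <- ncol(q) - state$lookahead
  if (n_emit <= 0L) {
    state$delay <- q
    return(list(out = q[, 0L, drop = FALSE], state = state))
  }
  emit <- q[, seq_len(n_emit), drop = FALSE]
  state$delay <- q[, n_emit + seq_len(state$lookahead), drop = FALSE]
  list(out = emit, state = state)
}

# one detection + operator update; returns updated state
update_operator <- function(state, cov, calib, params) {
  det <- detect_components(cov, calib, params$maxdims)
  state$n_decompositions <- state$n_decompositions + 1L
  if (!all(det$clean_mask)) state$n_flagged <- state$n_flagged + 1L
  R_new <- reconstruction_operator(calib$M, det$V, det$clean_mask)
  if (is.null(R_new)) {            # degenerate window: hold the previous
    state$R_new <- state$R_prev
    state$new_trivial <- state$prev_trivial
  } else {
    state$R_new <- R_new
    state$new_trivial <- all(det$clean_mask)
  }
  state
}

# process one analysis segment (raw + shaped samples); returns list(out,
# state). The segment may be shorter than `range` only at flush time.
process_segment <- function(raw, shaped, calib, params, state) {
  riem <- identical(params$geometry, "riemannian")
  outs <- list()
  if (riem) {
    C <- sample_covariance_unbiased(shaped)
    U <- smooth_covariance_riemannian(C, state$prev_seg_cov, 0.5)
    state$prev_seg_cov <- C
    state <- update_operator(state, U, calib, params)
    em <- emit_through_delay(state, raw)
    state <- em$state
    out <- crossfade_apply(em$out, state$R_prev, state$R_new,
                           state$prev_trivial, state$new_trivial,
                           ramp = params$stepsize)
    state$R_prev <- state$R_new
    state$prev_trivial <- state$new_trivial
    outs <- list(out)
  } else {
    starts <- seq.int(1L, ncol(raw), by = params$stepsize)
    for (s0 in starts) {
      cols <- s0:min(s0 + params$stepsize - 1L, ncol(raw))
      # sliding one-window covariance: uniform weighted average of the
      # chunk covariances spanning the trailing `range` shaped samples
      state$shaped_hist <- cbind(state$shaped_hist,
                                 shaped[, cols, drop = FALSE])
      nh <- ncol(state$shaped_hist)
      if (nh > state$range)
        state$shaped_hist <-
          state$shaped_hist[, nh - state$range + seq_len(state$range),
                            drop = FALSE]
      H <- state$shaped_hist
      U <- tcrossprod(H) / ncol(H)
      U <- (U + t(U)) / 2
      state <- update_operator(state, U, calib, params)
      em <- emit_through_delay(state, raw[, cols, drop = FALSE])
      state <- em$state
      outs[[length(outs) + 1L]] <-
        crossfade_apply(em$out, state$R_prev, state$R_new,
                        state$prev_trivial, state$new_trivial)
      state$R_prev <- state$R_new
      state$prev_trivial <- state$new_trivial
    }
  }
  list(out = do.call(cbind, outs), state = state)
}

#' Process EEG through ASR / rASR (streaming)
#'
#' Consumes a chunk of consecutive samples and returns the cleaned samples
#' available so far, plus the updated state. Repeated calls with
#' consecutive chunks reproduce a single offline call exactly; samples of
#' an incomplete trailing analysis window (plus the internal lookahead)
#' stay buffered until the next call or [asr_flush()].
#'
#' @param x an [eeg_segment()] with the same montage and sampling rate as
#'   the calibration.
#' @param calib an [asr_calibrate()] result.
#' @param params an [asr_params()] object.
#' @param state an `asr_state`, or `NULL` to start a new stream.
#' @return list with `data` (cleaned [eeg_segment()], possibly zero
#'   samples) and `state`.
#' @export
asr_process <- function(x, calib, params, state = NULL) {
  stopifnot(inherits(x, "eeg_segment"), inherits(calib, "asr_calibration"))
  if (!identical(x$labels, calib$labels) || x$srate != calib$srate)
    stop("incompatible calibration: montage or sampling rate mismatch")
  if (is.null(state)) state <- asr_new_state(calib, params)
  buf <- cbind(state$buffer, x$data)
  range <- state$range
  n_full <- ncol(buf) %/% range
  outs <- vector("list", n_full)
  if (n_full > 0L) {
    for (i in seq_len(n_full)) {
      cols <- (i - 1L) * range + seq_len(range)
      raw <- buf[, cols, drop = FALSE]
      if (is.null(calib$shaping)) {
        shaped <- raw
      } else {
        sh <- shape_signal(raw, calib$shaping, state$shape_carry)
        shaped <- sh$shaped
        state$shape_carry <- sh$carry
      }
      res <- process_segment(raw, shaped, calib, params, state)
      state <- res$state
      outs[[i]] <- res$out
    }
  }
  state$buffer <- buf[, seq_len(ncol(buf) - n_full * range) +
                        n_full * range, drop = FALSE]
  out <- if (n_full > 0L) do.call(cbind, outs) else
    matrix(0, nrow(buf), 0L)
  rownames(out) <- x$labels
  list(data = structure(list(data = out, srate = x$srate,
                             labels = x$labels), class = "eeg_segment"),
       state = state)
}

#' Flush the tail of a stream
#'
#' Processes the remaining buffered samples (an incomplete analysis
#' window, if any) and drains the internal delay queue with the final
#' reconstruction operator, so that the concatenated stream output has
#' exactly the length of the stream input.
#'
#' @inheritParams asr_process
#' @return list with `data` and `state`, as [asr_process()].
#' @export
asr_flush <- function(calib, params, state) {
  c_n <- length(calib$labels)
  nb <- ncol(state$buffer)
  parts <- list()
  if (nb >= 2L) {
    raw <- state$buffer
    if (is.null(calib$shaping)) {
      shaped <- raw
    } else {
      sh <- shape_signal(raw, calib$shaping, state$shape_carry)
      shaped <- sh$shaped
      state$shape_carry <- sh$carry
    }
    res <- process_segment(raw, shaped, calib, params, state)
    state <- res$state
    parts <- list(res$out)
  } else if (nb == 1L) {
    em <- emit_through_delay(state, state$buffer)
    state <- em$state
    parts <- list(if (state$prev_trivial) em$out else
      state$R_prev %*% em$out)
  }
  if (ncol(state$delay) > 0L) {
    tailX <- state$delay
    parts[[length(parts) + 1L]] <-
      if (state$prev_trivial) tailX else state$R_prev %*% tailX
    state$delay <- tailX[, 0L, drop = FALSE]
  }
  state$buffer <- matrix(0, c_n, 0L)
  out <- if (length(parts)) do.call(cbind, parts) else matrix(0, c_n, 0L)
  rownames(out) <- calib$labels
  list(data = structure(list(data = out, srate = calib$srate,
                             labels = calib$labels),
                        class = "eeg_segment"),
       state = state)
}

#' Clean a recording offline
#'
#' Convenience wrapper: streams the whole recording through
#' [asr_process()] and [asr_flush()] and returns a full-length cleaned
#' segment. The number of detection eigendecompositions performed and the
#' number of detections that flagged at least one component are attached
#' as attributes `n_decompositions` and `n_flagged`.
#'
#' @inheritParams asr_process
#' @return cleaned [eeg_segment()] of the same length as `x`.
#' @export
asr_clean <- function(x, calib, params) {
  r1 <- asr_process(x, calib, params)
  r2 <- asr_flush(calib, params, r1$state)
  out <- eeg_segment(cbind(r1$data$data, r2$data$data), x$srate, x$labels)
  attr(out, "n_decompositions") <- r2$state$n_decompositions
  attr(out, "n_flagged") <- r2$state$n_flagged
  out
}
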