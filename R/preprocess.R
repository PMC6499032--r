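# Pre-correction stages: band-limiting FIR filters, flatline channel
# detection, drift removal, and the spectral-shaping filter applied before
# covariance estimation. Pipeline order is flatlines -> drifts -> subspace
# reconstruction.

# FFT-based convolution of each row of X (c x t) with FIR taps b
conv_rows_fft <- function(X, b) {
  n <- ncol(X)
  L <- length(b)
  nfft <- stats::nextn(n + L - 1L, 2)
  B <- stats::fft(c(b, rep(0, nfft - L)))
  out <- matrix(0, nrow(X), n + L - 1L)
  for (i in seq_len(nrow(X))) {
    Xi <- stats::fft(c(X[i, ], rep(0, nfft - n)))
    y <- Re(stats::fft(Xi * B, inverse = TRUE)) / nfft
    out[i, ] <- y[seq_len(n + L - 1L)]
  }
  out
}

# Zero-phase application of a linear-phase FIR: reflection-pad, convolve,
# compensate the group delay (order/2), trim. Causal mode convolves without
# delay compensation.
apply_fir <- function(X, b, zero_phase = TRUE) {
  n <- ncol(X)
  L <- length(b)
  if (!zero_phase) {
    y <- conv_rows_fft(X, b)
    return(y[, seq_len(n), drop = FALSE])
  }
  pad <- L - 1L
  if (n <= pad + 1L) stop("too-short input: segment shorter than filter order")
  left <- X[, pad:1L + 1L, drop = FALSE]    # reflection, excluding endpoint
  right <- X[, n - seq_len(pad), drop = FALSE]
  Xp <- cbind(2 * X[, 1L] - left, X, 2 * X[, n] - right)
  y <- conv_rows_fft(Xp, b)
  g <- (L - 1L) %/% 2L
  y[, pad + g + seq_len(n), drop = FALSE]
}

#' Band-limiting FIR filters
#'
#' Low-pass at `lp_hz` and high-pass at `hp_hz`, both linear-phase FIR
#' (Hamming design) applied zero-phase by default (group delay
#' compensated with reflection padding), matching standard offline ERP
#' practice. Set `zero_phase = FALSE` for the causal online path, which
#' then carries a group delay of half the filter order.
#'
#' @param x an [eeg_segment()].
#' @param lp_hz low-pass edge in Hz (default 40).
#' @param lp_order low-pass FIR order (default 166).
#' @param hp_hz high-pass edge in Hz (default 0.25).
#' @param hp_order high-pass FIR order (default 3300).
#' @param zero_phase compensate group delay (default `TRUE`).
#' @return filtered [eeg_segment()].
#' @export
bandpass_fir <- function(x, lp_hz = 40, lp_order = 166L,
                         hp_hz = 0.25, hp_order = 3300L,
                         zero_phase = TRUE) {
  stopifnot(inherits(x, "eeg_segment"))
  ny <- x$srate / 2
  if (n_samples(x) <= max(lp_order, hp_order))
    stop("too-short input: segment shorter than filter order")
  b_lp <- signal::fir1(lp_order, lp_hz / ny, type = "low")
  b_hp <- signal::fir1(hp_order, hp_hz / ny, type = "high")
  X <- apply_fir(x$data, as.numeric(b_lp), zero_phase)
  X <- apply_fir(X, as.numeric(b_hp), zero_phase)
  eeg_segment(X, x$srate, x$labels)
}

#' Detect flatline channels
#'
#' A channel is flagged when it contains a run of at least
#' `max_flat_seconds * srate` consecutive samples whose absolute successive
#' differences stay below `tol` (default 1e-8 µV). Flagged channels are
#' only masked, never altered; the pipeline driver excludes them before
#' covariance estimation.
#'
#' @param x an [eeg_segment()].
#' @param max_flat_seconds run duration that qualifies as flat (s).
#' @param tol successive-difference tolerance in µV.
#' @return logical vector, one entry per channel (`TRUE` = flat).
#' @export
detect_flatlines <- function(x, max_flat_seconds, tol = 1e-8) {
  stopifnot(inherits(x, "eeg_segment"))
  if (n_samples(x) / x$srate <= max_flat_seconds)
    stop("recording shorter than the flatline duration")
  need <- max_flat_seconds * x$srate
  apply(x$data, 1L, function(ch) {
    flat <- abs(diff(ch)) < tol
    if (!any(flat)) return(FALSE)
    r <- rle(flat)
    max(r$lengths[r$values]) + 1L >= need
  })
}

#' Remove slow drifts
#'
#' High-pass filter with the stated transition band (stop-band edge,
#' pass-band edge in Hz); a Hamming-window FIR with cutoff at the band
#' midpoint and order set by the transition width, applied zero-phase by
#' default.
#'
#' @param x an [eeg_segment()].
#' @param transition_band length-2 numeric, `(stop, pass)` edge in Hz
#'   (default `c(0.25, 0.95)`).
#' @param zero_phase compensate group delay (default `TRUE`).
#' @return filtered [eeg_segment()], per-channel mean near zero.
#' @export
remove_drifts <- function(x, transition_band = c(0.25, 0.95),
                          zero_phase = TRUE) {
  stopifnot(inherits(x, "eeg_segment"), length(transition_band) == 2L)
  ny <- x$srate / 2
  width <- diff(transition_band)
  if (width <= 0) stop("transition band must be increasing")
  order <- ceiling(3.3 * x$srate / width)
  order <- order + order %% 2L   # even order for a type-I high-pass
  if (n_samples(x) <= order)
    stop("too-short input: segment shorter than filter order")
  fc <- mean(transition_band) / ny
  b <- signal::fir1(order, fc, type = "high")
  eeg_segment(apply_fir(x$data, as.numeric(b), zero_phase),
              x$srate, x$labels)
}

# --- calibration spectral-shaping filter ------------------------------------
# Covariance statistics are calibrated on spectrally shaped data that
# approximates an inverse typical-EEG spectrum: low frequencies and
# >= 80 Hz boosted (x3), the 3-13 Hz range attenuated (x0.33-0.75), the
# 16-40 Hz band passed unchanged. The filter is realized as a causal
# minimum-phase FIR (cepstral construction from the target magnitude), so
# that the detection statistics stay time-aligned with the reconstructed
# samples; a linear-phase filter of useful length would delay detection by
# hundreds of milliseconds.

shaping_magnitude <- function(f_hz, srate) {
  ny <- srate / 2
  hi <- min(80, ny - 1)
  f <- c(0, 2, 3, 13, 16, 40, hi, ny)
  m <- c(3, 0.75, 0.33, 0.33, 1, 1, 3, 3)
  stats::approx(f, m, xout = pmin(f_hz, ny), rule = 2)$y
}

#' Design the minimum-phase spectral-shaping FIR
#'
#' @param srate sampling rate in Hz.
#' @param n_taps filter length; default `round(srate)` (one second).
#' @return numeric vector of FIR taps.
#' @keywords internal
design_shaping_fir <- function(srate, n_taps = round(srate)) {
  nfft <- 4096L
  f <- seq(0, srate / 2, length.out = nfft / 2 + 1L)
  mag <- pmax(shaping_magnitude(f, srate), 1e-4)
  mag_full <- c(mag, rev(mag[2:(nfft / 2)]))
  # real cepstrum -> fold anticausal part onto causal -> minimum phase
  cep <- Re(stats::fft(log(mag_full), inverse = TRUE)) / nfft
  fold <- cep
  fold[2:(nfft / 2)] <- 2 * cep[2:(nfft / 2)]
  fold[(nfft / 2 + 2):nfft] <- 0
  h <- Re(stats::fft(exp(stats::fft(fold)), inverse = TRUE)) / nfft
  h[seq_len(n_taps)]
}

# Causal shaped signal with streaming state (carry of the last n_taps - 1
# raw input samples), so chunked calls reproduce the offline result.
shape_signal <- function(X, b, carry = NULL) {
  L <- length(b)
  if (is.null(carry)) carry <- matrix(0, nrow(X), L - 1L)
  Xp <- cbind(carry, X)
  y <- conv_rows_fft(Xp, b)
  out <- y[, (L - 1L) + seq_len(ncol(X)), drop = FALSE]
  new_carry <- Xp[, ncol(Xp) - (L - 2L):0, drop = FALSE]
  list(shaped = out, carry = new_carry)
}
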