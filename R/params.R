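# Parameter sets for the two correction methods.
#
# Published per-method values (rASR, ASR): flatline (1, 5) s,
# hp transition (0.25, 0.95) Hz for both, cutoff (1, 5), window (0.3, 0.5) s,
# stepsize (16, 32) samples, maxdims (1, 0.66). rASR uses the more
# aggressive cutoff/stepsize because its covariance model is updated once
# per analysis window instead of once per stepsize chunk.

#' ASR / rASR parameter set
#'
#' Resolves the per-method published defaults and applies any overrides.
#' `maxdims` values in (0, 1] are interpreted as the reconstructable
#' fraction of dimensions (so 1 means "all"), values > 1 as a count.
#' A `burst` entry, if supplied (legacy wrapper naming), is treated as an
#' alias for `cutoff`; an explicit `cutoff` takes precedence.
#'
#' @param method `"rasr"` (Riemannian geometry) or `"asr"` (Euclidean).
#' @param ... overrides for any field: `cutoff`, `window` (s), `stepsize`
#'   (samples), `maxdims`, `flatline` (s), `hp_band` (length-2 Hz),
#'   `geometry` (`"riemannian"`/`"euclidean"`), `use_shaping_filter`,
#'   `robust_stats`, `riemannian_calibration`, `karcher_history`, `burst`.
#' @return a list of class `asr_params`.
#' @export
asr_params <- function(method = c("rasr", "asr"), ...) {
  method <- match.arg(method)
  p <- if (method == "rasr") {
    list(method = "rasr", cutoff = 1, window = 0.3, stepsize = 16L,
         maxdims = 1.0, flatline = 1, hp_band = c(0.25, 0.95),
         geometry = "riemannian", riemannian_calibration = TRUE)
  } else {
    list(method = "asr", cutoff = 5, window = 0.5, stepsize = 32L,
         maxdims = 0.66, flatline = 5, hp_band = c(0.25, 0.95),
         geometry = "euclidean", riemannian_calibration = FALSE)
  }
  p$use_shaping_filter <- TRUE
  p$robust_stats <- TRUE
  p$karcher_history <- 1L   # previous segments entering the Karcher mean
  ov <- list(...)
  if (!is.null(ov$burst) && is.null(ov$cutoff)) ov$cutoff <- ov$burst
  ov$burst <- NULL
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  if (p$window <= 0) stop("window must be positive")
  if (p$stepsize < 1) stop("stepsize must be >= 1")
  if (p$cutoff <= 0) stop("cutoff must be positive")
  if (p$maxdims <= 0) stop("maxdims must be positive")
  p$stepsize <- as.integer(p$stepsize)
  class(p) <- "asr_params"
  p
}

# resolve maxdims to a count of removable dimensions for c channels
resolve_maxdims <- function(maxdims, c) {
  k <- if (maxdims <= 1) round(maxdims * c) else round(maxdims)
  max(1L, min(as.integer(k), c))
}

# analysis-window length in samples; round half away from zero
resolve_range <- function(srate, window) {
  r <- floor(srate * window + 0.5)
  max(2L, as.integer(r))
}

#' @export
print.asr_params <- function(x, ...) {
  cat(sprintf(
    "<asr_params> method=%s geometry=%s cutoff=%g window=%gs stepsize=%d maxdims=%g\n",
    x$method, x$geometry, x$cutoff, x$window, x$stepsize, x$maxdims))
  invisible(x)
}
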