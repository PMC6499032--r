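# Shared fixtures, built lazily and cached for the whole test run.

# random SPD matrix with eigenvalues in [lo, hi]
rand_spd <- function(c, seed = NULL, lo = 0.5, hi = 2) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(c * c), c)))
  lam <- runif(c, lo, hi)
  Q %*% (lam * t(Q))
}

# random invertible matrix
rand_invertible <- function(c, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    W <- matrix(rnorm(c * c), c)
    if (abs(det(W)) > 1e-3) return(W)
  }
}

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# small synthetic session (60 s task) used across evaluation/processing tests
fx_session <- function() {
  fx_get("session", function() generate_session(list(task_s = 60), seed = 11))
}

# drift-removed calibration segment + fitted model per method
fx_calibration <- function(method = "asr") {
  fx_get(paste0("cal_", method), function() {
    p <- asr_params(method)
    seg <- remove_drifts(fx_session()$calibration, p$hp_band)
    list(params = p, calseg = seg, cal = asr_calibrate(seg, p))
  })
}

# cleaned task data per method (shares the session fixture)
fx_cleaned <- function(method = "asr") {
  fx_get(paste0("cleaned_", method), function() {
    cc <- fx_calibration(method)
    task <- remove_drifts(fx_session()$task, cc$params$hp_band)
    list(task = task, cleaned = asr_clean(task, cc$cal, cc$params))
  })
}
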