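# Synthetic mobile-EEG sessions with ground truth: spatially correlated 1/f
# background, frontal eye-blinks, occipital visual-evoked potentials, and a
# clean calibration stretch. Emulates a 24-channel, 250 Hz mobile recording.
# Task data are exactly background + injected components, so signal and
# artifact can be separated for scoring.

# evaluate expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Standard 24-channel 10/20 montage with 2D positions
#'
#' Channel labels and approximate 2D scalp-projection coordinates
#' (x = right, y = anterior, head rim at radius 1) for a standard
#' 24-channel mobile cap.
#'
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
montage_24 <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "Fz", "F7", "F8", "FC1", "FC2", "Cz",
              "C3", "C4", "T7", "T8", "CPz", "CP1", "CP2", "CP5",
              "CP6", "TP9", "TP10", "Pz", "P3", "P4", "O1", "O2"),
    x = c(-0.31, 0.31, 0, -0.81, 0.81, -0.22, 0.22, 0,
          -0.5, 0.5, -1, 1, 0, -0.22, 0.22, -0.67,
          0.67, -0.95, 0.95, 0, -0.39, 0.39, -0.31, 0.31),
    y = c(0.95, 0.95, 0.5, 0.59, 0.59, 0.27, 0.27, 0,
          0, 0, 0, 0, -0.25, -0.27, -0.27, -0.28,
          -0.28, -0.31, -0.31, -0.5, -0.59, -0.59, -0.95, -0.95),
    stringsAsFactors = FALSE)
}

# exponential distance fall-off topography from a scalp focus, normalized so
# the mean weight over `ref_labels` equals 1
focal_topography <- function(montage, focus_xy, lambda, ref_labels) {
  d <- sqrt((montage$x - focus_xy[1])^2 + (montage$y - focus_xy[2])^2)
  w <- exp(-d / lambda)
  ref <- montage$label %in% ref_labels
  w / mean(w[ref])
}

#' Generate spatially correlated 1/f background EEG
#'
#' Independent latent 1/f^alpha sources (one per electrode site, random
#' Fourier phases) are mixed through a fixed Gaussian spatial kernel over
#' the montage so neighbouring channels are correlated; each channel is
#' then scaled to the target RMS.
#'
#' @param c number of channels (default 24, the supported montage).
#' @param duration_s duration in seconds (>= 1).
#' @param srate sampling rate in Hz (default 250).
#' @param rms_uV per-channel target RMS in µV (default 10, a typical
#'   band-limited resting-EEG amplitude).
#' @param spectral_exponent alpha of the 1/f^alpha amplitude spectrum
#'   (default 1.5; 0 gives white noise).
#' @param sensor_noise_uV RMS of independent white sensor noise added per
#'   channel (default 1 µV, a typical mobile-amplifier noise floor; keeps
#'   channel covariances full rank, as real hardware does).
#' @param modulation_cv coefficient of variation of the slow log-normal
#'   amplitude envelopes applied to every latent source and to each
#'   channel's sensor noise (default 0.4, timescale ~2 s). Mobile EEG is
#'   strongly amplitude-nonstationary (rhythm waxing/waning, gait and
#'   electrode-contact fluctuations); 0 gives a stationary process.
#' @param seed integer RNG seed (the generator is a pure function of its
#'   arguments and the seed).
#' @return an [eeg_segment()].
#' @export
generate_background <- function(c = 24L, duration_s, srate = 250,
                                rms_uV = 10, spectral_exponent = 1.5,
                                sensor_noise_uV = 1, modulation_cv = 0.4,
                                seed = NULL) {
  if (duration_s < 1) stop("duration must be at least 1 s")
  mont <- montage_24()
  if (c > nrow(mont)) stop("montage supports up to 24 channels")
  mont <- mont[seq_len(c), , drop = FALSE]
  n <- round(duration_s * srate)
  with_seed(seed, {
    f <- seq(0, srate / 2, length.out = floor(n / 2) + 1L)
    amp <- c(0, f[-1L]^(-spectral_exponent / 2))
    # slow log-normal amplitude envelope, unit mean-square, CV = cv
    envelope <- function() {
      if (modulation_cv <= 0) return(rep(1, n))
      sig <- sqrt(log(1 + modulation_cv^2))
      z <- stats::rnorm(n)
      k <- round(2 * srate)           # ~2 s timescale
      kern <- exp(-0.5 * (seq(-3, 3, length.out = 2L * k + 1L))^2)
      kern <- kern / sqrt(sum(kern^2))
      zs <- conv_rows_fft(matrix(z, 1L), kern)[1L, k + seq_len(n)]
      e <- exp(sig * zs)
      e / sqrt(mean(e^2))
    }
    S <- matrix(0, c, n)
    for (i in seq_len(c)) {
      # Hermitian spectrum with random phases -> real 1/f series
      half <- amp * exp(2i * pi * stats::runif(length(amp)))
      half[1L] <- 0
      if (n %% 2L == 0L) half[length(half)] <- Re(half[length(half)])
      spec <- c(half, Conj(rev(half[2:(length(half) - (n %% 2L == 0L))])))
      S[i, ] <- Re(stats::fft(spec[seq_len(n)], inverse = TRUE)) * envelope()
    }
    D2 <- outer(mont$x, mont$x, `-`)^2 + outer(mont$y, mont$y, `-`)^2
    A <- exp(-D2 / (2 * 0.5^2))
    X <- A %*% S
    rms <- sqrt(rowMeans(X^2))
    X <- X * (rms_uV / rms)
    if (sensor_noise_uV > 0) {
      N <- matrix(stats::rnorm(c * n, sd = sensor_noise_uV), c, n)
      for (i in seq_len(c)) N[i, ] <- N[i, ] * envelope()
      X <- X + N
    }
    eeg_segment(X, srate, mont$label)
  })
}

# biphasic blink waveform, unit peak, ~300 ms main bump with a mild
# negative rebound; returns (times_s, values)
blink_waveform <- function(srate) {
  t <- seq(-0.25, 0.45, by = 1 / srate)
  w <- exp(-abs(t / 0.09)^2.2) - 0.12 * exp(-((t - 0.22) / 0.12)^2)
  list(t = t, w = w / max(w), peak_idx = which.max(w))
}

#' Inject frontal eye-blinks
#'
#' Adds stereotypical biphasic blinks with a frontally focal topography
#' (maximal at Fp1/Fp2, exponential fall-off toward occipital sites; the
#' occipital weight is below 20% of the frontal weight). Blink onsets are
#' drawn from a renewal process with a hard refractory gap; the blink-locked
#' average at Fp1/Fp2 peaks at `peak_uV`.
#'
#' @param x an [eeg_segment()].
#' @param rate_per_min mean blink rate (default 40/min).
#' @param peak_uV blink peak amplitude at the frontopolar channels
#'   (default 254.92 µV, a typical indoor mobile-EEG blink mean).
#' @param topo optional channel weight vector; default frontal fall-off.
#' @param seed RNG seed.
#' @param refractory_s minimum gap between blink peaks (default 0.5 s).
#' @return list with `segment` (data plus blinks), `times` (peak sample
#'   indices), `topo`, and `component` (the injected channels-by-samples
#'   blink signal alone).
#' @export
inject_blinks <- function(x, rate_per_min = 40, peak_uV = 254.92,
                          topo = NULL, seed = NULL, refractory_s = 0.5) {
  stopifnot(inherits(x, "eeg_segment"))
  mont <- montage_24()[seq_len(n_channels(x)), ]
  if (is.null(topo))
    topo <- focal_topography(mont, c(0, 1.0), 0.55, c("Fp1", "Fp2"))
  wf <- blink_waveform(x$srate)
  n <- n_samples(x)
  comp <- matrix(0, n_channels(x), n)
  times <- integer(0)
  if (rate_per_min > 0) {
    r <- rate_per_min / 60
    if (1 / r <= refractory_s)
      stop("blink rate incompatible with the refractory gap")
    lam <- 1 / (1 / r - refractory_s)
    times <- with_seed(seed, {
      tt <- numeric(0)
      cur <- 0.5 + stats::rexp(1L, lam)
      margin <- 0.5
      while (cur < n / x$srate - margin) {
        tt <- c(tt, cur)
        cur <- cur + refractory_s + stats::rexp(1L, lam)
      }
      round(tt * x$srate)
    })
    for (s in times) {
      idx <- s + seq_along(wf$t) - wf$peak_idx
      ok <- idx >= 1L & idx <= n
      comp[, idx[ok]] <- comp[, idx[ok]] +
        peak_uV * outer(topo, wf$w[ok])
    }
  }
  list(segment = eeg_segment(x$data + comp, x$srate, x$labels),
       times = as.integer(times), topo = topo, component = comp)
}

# VEP waveform: positive P1 and negative N1 deflection (unit amplitudes
# scaled by the caller), Gaussian lobes at the requested latencies
vep_waveform <- function(srate, p1_uV, n1_uV, p1_ms, n1_ms) {
  t <- seq(0, 0.5, by = 1 / srate)
  w <- p1_uV * exp(-((t - p1_ms / 1000) / 0.015)^2) +
    n1_uV * exp(-((t - n1_ms / 1000) / 0.025)^2)
  list(t = t, w = w)
}

#' Inject occipital visual-evoked potentials
#'
#' Adds a stimulus-locked response with an early positive (P1) and a later
#' negative (N1) deflection, focal over O1/O2.
#'
#' @param x an [eeg_segment()].
#' @param event_times stimulus sample indices (1-based).
#' @param p1_uV,n1_uV P1 and N1 amplitudes in µV (defaults +5, -10).
#' @param p1_ms,n1_ms peak latencies in ms (defaults 100, 170).
#' @param topo optional channel weights; default occipital fall-off
#'   normalized to mean(O1, O2) = 1.
#' @param seed unused (kept for generator API symmetry; injection is
#'   deterministic given the event times).
#' @return list with `segment`, `times`, `topo`, `component`.
#' @export
inject_vep <- function(x, event_times, p1_uV = 5, n1_uV = -10,
                       p1_ms = 100, n1_ms = 170, topo = NULL, seed = NULL) {
  stopifnot(inherits(x, "eeg_segment"))
  n <- n_samples(x)
  if (length(event_times) && (min(event_times) < 1L || max(event_times) > n))
    stop("event times outside the recording")
  mont <- montage_24()[seq_len(n_channels(x)), ]
  if (is.null(topo))
    topo <- focal_topography(mont, c(0, -0.95), 0.55, c("O1", "O2"))
  wf <- vep_waveform(x$srate, p1_uV, n1_uV, p1_ms, n1_ms)
  comp <- matrix(0, n_channels(x), n)
  for (s in event_times) {
    idx <- s + seq_along(wf$t) - 1L
    ok <- idx <= n
    comp[, idx[ok]] <- comp[, idx[ok]] + outer(topo, wf$w[ok])
  }
  list(segment = eeg_segment(x$data + comp, x$srate, x$labels),
       times = as.integer(event_times), topo = topo, component = comp)
}

#' Generate a complete synthetic session with ground truth
#'
#' A clean 60 s calibration stretch (background only) plus a task stretch
#' containing eye-blinks and VEP events, both from the same montage and
#' background model. The task data equal background + blink component +
#' VEP component exactly.
#'
#' @param config list of overrides: `n_channels`, `srate`,
#'   `calibration_s` (60), `task_s` (300), `rms_uV` (10),
#'   `spectral_exponent` (1.5), `blink_rate_per_min` (40),
#'   `blink_peak_uV` (254.92), `vep_interval_s` (2), `p1_uV` (5),
#'   `n1_uV` (-10), `p1_ms` (100), `n1_ms` (170).
#' @param seed integer seed; the session is a pure function of
#'   (config, seed).
#' @return object of class `synthetic_session`: `calibration`, `task`
#'   ([eeg_segment()]s), `blink_times`, `vep_times`, `blink_topo`,
#'   `vep_topo`, `components` (background/blink/vep matrices), `config`,
#'   `seed`.
#' @export
generate_session <- function(config = list(), seed = 1L) {
  cfg <- list(n_channels = 24L, srate = 250, calibration_s = 60,
              task_s = 300, rms_uV = 10, spectral_exponent = 1.5,
              blink_rate_per_min = 40, blink_peak_uV = 254.92,
              vep_interval_s = 2, p1_uV = 5, n1_uV = -10,
              p1_ms = 100, n1_ms = 170)
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  seed <- as.integer(seed)

  calib <- generate_background(cfg$n_channels, cfg$calibration_s, cfg$srate,
                               cfg$rms_uV, cfg$spectral_exponent,
                               seed = seed)
  bg <- generate_background(cfg$n_channels, cfg$task_s, cfg$srate,
                            cfg$rms_uV, cfg$spectral_exponent,
                            seed = seed + 1000L)
  bl <- inject_blinks(bg, cfg$blink_rate_per_min, cfg$blink_peak_uV,
                      seed = seed + 2000L)
  vep_times <- with_seed(seed + 3000L, {
    base <- if (cfg$task_s - 1 >= 5)
      seq(5, cfg$task_s - 1, by = cfg$vep_interval_s) else numeric(0)
    round((base + stats::runif(length(base), -0.2, 0.2)) * cfg$srate)
  })
  vp <- inject_vep(bl$segment, vep_times, cfg$p1_uV, cfg$n1_uV,
                   cfg$p1_ms, cfg$n1_ms)
  structure(list(
    calibration = calib,
    task = vp$segment,
    blink_times = bl$times,
    vep_times = vp$times,
    blink_topo = bl$topo,
    vep_topo = vp$topo,
    components = list(background = bg$data, blinks = bl$component,
                      veps = vp$component),
    config = cfg, seed = seed), class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> seed=%d, %d ch @ %g Hz, calib %.0f s, task %.0f s\n",
    x$seed, n_channels(x$task), x$task$srate,
    n_samples(x$calibration) / x$calibration$srate,
    n_samples(x$task) / x$task$srate))
  cat(sprintf("  %d blinks, %d VEP events\n",
              length(x$blink_times), length(x$vep_times)))
  invisible(x)
}

#' Write a synthetic session to a directory
#'
#' Writes `calibration.eeg` and `task.eeg` (plain-text containers) and
#' `events.tsv` (sample, type) with ground-truth blink and VEP events.
#'
#' @param session a [generate_session()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_eeg(session$calibration, file.path(dir, "calibration.eeg"))
  write_eeg(session$task, file.path(dir, "task.eeg"))
  ev <- rbind(
    data.frame(sample = session$blink_times,
               type = rep("blink", length(session$blink_times))),
    data.frame(sample = session$vep_times,
               type = rep("vep", length(session$vep_times))))
  ev <- ev[order(ev$sample), ]
  write_events(ev, file.path(dir, "events.tsv"))
  invisible(dir)
}
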