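# Evaluation of correction quality on three axes: eye-blink suppression
# (sensitivity: blink-locked frontal amplitude and blink-topography
# similarity), VEP retention (specificity: N1 amplitude and SNR in dB),
# and decomposition-count efficiency.

#' Detect eye-blinks from the frontal channels
#'
#' Robust threshold detector on the smoothed mean of the frontopolar
#' channels: samples exceeding `median + 3 * scaled-MAD` are grouped into
#' suprathreshold runs, each contributing its peak sample, with a 500 ms
#' refractory gap between accepted peaks. (A template-learning blink
#' detector is unnecessary here because synthetic sessions carry ground
#' truth; this detector is a deliberate simplification.)
#'
#' @param x an [eeg_segment()].
#' @param frontal_labels channels to combine (default Fp1, Fp2).
#' @param smooth_s moving-average smoothing length in seconds
#'   (default 0.1).
#' @param refractory_s minimum separation of accepted peaks (default 0.5).
#' @return integer vector of blink peak sample indices.
#' @export
detect_blinks <- function(x, frontal_labels = c("Fp1", "Fp2"),
                          smooth_s = 0.1, refractory_s = 0.5) {
  stopifnot(inherits(x, "eeg_segment"))
  if (!all(frontal_labels %in% x$labels))
    stop("montage error: missing frontal channel(s) ",
         paste(setdiff(frontal_labels, x$labels), collapse = ", "))
  y <- colMeans(x$data[match(frontal_labels, x$labels), , drop = FALSE])
  k <- max(1L, round(smooth_s * x$srate))
  ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  ys[is.na(ys)] <- 0
  thr <- stats::median(ys) + 3 * stats::mad(ys)
  above <- ys > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer(0)
  for (i in which(r$values)) {
    seg <- starts[i]:ends[i]
    peaks <- c(peaks, seg[which.max(ys[seg])])
  }
  refr <- refractory_s * x$srate
  keep <- integer(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last >= refr) {
      keep <- c(keep, p)
      last <- p
    }
  }
  keep
}

#' Epoch a recording around events
#'
#' Extracts fixed-length epochs around each event and subtracts the
#' per-channel mean of the baseline interval. Events too close to the
#' recording edges are dropped (recorded in the `dropped` field).
#'
#' @param x an [eeg_segment()].
#' @param events event sample indices (1-based).
#' @param window_ms length-2 epoch limits in ms relative to the event,
#'   e.g. `c(-200, 500)`.
#' @param baseline_ms length-2 baseline interval in ms (inside the epoch);
#'   `NULL` skips baseline correction.
#' @return object of class `eeg_epochs`: `data` (n_epochs x c x t array),
#'   `times` (ms), `events` (retained), `dropped`, `srate`, `labels`.
#' @export
epoch_data <- function(x, events, window_ms = c(-200, 500),
                       baseline_ms = c(-200, 0)) {
  stopifnot(inherits(x, "eeg_segment"), length(window_ms) == 2L)
  srate <- x$srate
  rel <- seq(round(window_ms[1] / 1000 * srate),
             round(window_ms[2] / 1000 * srate))
  times <- rel / srate * 1000
  n <- n_samples(x)
  ok <- events + min(rel) >= 1L & events + max(rel) <= n
  kept <- events[ok]
  arr <- array(0, c(length(kept), n_channels(x), length(rel)))
  bidx <- if (is.null(baseline_ms)) integer(0) else
    which(times >= baseline_ms[1] & times <= baseline_ms[2])
  for (i in seq_along(kept)) {
    E <- x$data[, kept[i] + rel, drop = FALSE]
    if (length(bidx))
      E <- E - rowMeans(E[, bidx, drop = FALSE])
    arr[i, , ] <- E
  }
  structure(list(data = arr, times = times, events = kept,
                 dropped = events[!ok], srate = srate, labels = x$labels),
            class = "eeg_epochs")
}

# average epochs into an evoked channels-by-time matrix
evoked_mean <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  apply(epochs$data, c(2L, 3L), mean)
}

#' Evoked-response signal-to-noise ratio in decibels
#'
#' `dB = 10 * log10(|peak| / baseline SD)`, with the noise estimated as
#' the standard deviation of the mean-channel evoked signal in the
#' pre-stimulus interval.
#'
#' @param evoked channels-by-time evoked matrix (µV).
#' @param times time axis in ms.
#' @param channels row indices (or labels present in `rownames`) averaged
#'   before peak picking.
#' @param peak_window_ms search window for the peak (ms).
#' @param baseline_ms pre-stimulus noise interval (default `c(-200, 0)`).
#' @return SNR in dB.
#' @export
vep_snr <- function(evoked, times, channels, peak_window_ms = c(120, 250),
                    baseline_ms = c(-200, 0)) {
  if (is.character(channels)) channels <- match(channels, rownames(evoked))
  y <- colMeans(evoked[channels, , drop = FALSE])
  bl <- y[times >= baseline_ms[1] & times <= baseline_ms[2]]
  noise <- stats::sd(bl)
  if (!is.finite(noise) || noise <= 0)
    stop("degenerate baseline: zero pre-stimulus standard deviation")
  win <- times >= peak_window_ms[1] & times <= peak_window_ms[2]
  peak <- max(abs(y[win]))
  10 * log10(peak / noise)
}

#' N1 amplitude and latency
#'
#' Most negative value (a signed minimum, not an extremum by magnitude)
#' of the mean of the occipital channels within the search window.
#'
#' @param evoked channels-by-time evoked matrix.
#' @param times time axis in ms.
#' @param channels rows (indices or labels) to average (default O1, O2 by
#'   label).
#' @param search_window_ms N1 search window (default 120-250 ms).
#' @return list with `amplitude` (µV) and `latency` (ms).
#' @export
n1_amplitude <- function(evoked, times, channels = c("O1", "O2"),
                         search_window_ms = c(120, 250)) {
  if (is.character(channels)) channels <- match(channels, rownames(evoked))
  y <- colMeans(evoked[channels, , drop = FALSE])
  win <- which(times >= search_window_ms[1] & times <= search_window_ms[2])
  if (!length(win)) stop("search window outside the epoch")
  j <- win[which.min(y[win])]
  list(amplitude = y[j], latency = times[j])
}

#' Similarity of two scalp topographies
#'
#' Channel-wise Pearson correlation, its square, and the Fisher
#' z-transform (r clipped to `1 - 1e-12` in magnitude so z stays finite).
#'
#' @param topo_a,topo_b numeric channel-weight vectors (length >= 3).
#' @return list with `r`, `r_squared`, `fisher_z`.
#' @export
topography_similarity <- function(topo_a, topo_b) {
  if (length(topo_a) != length(topo_b) || length(topo_a) < 3L)
    stop("topographies must have equal length >= 3")
  if (stats::sd(topo_a) == 0 || stats::sd(topo_b) == 0)
    stop("degenerate topography: zero variance")
  r <- stats::cor(topo_a, topo_b)
  rc <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  list(r = r, r_squared = r^2, fisher_z = atanh(rc))
}

#' Decomposition count of a processed recording
#'
#' Hardware-independent efficiency proxy: the number of detection
#' eigendecompositions performed while cleaning. Accepts an
#' [asr_clean()] result (attribute) or an `asr_state`.
#'
#' @param x cleaned segment or processing state.
#' @return integer count.
#' @export
decomposition_counter <- function(x) {
  if (inherits(x, "asr_state")) return(x$n_decompositions)
  n <- attr(x, "n_decompositions")
  if (is.null(n)) stop("object carries no decomposition count")
  n
}

# blink-locked peak of the mean frontal channels of an evoked matrix
blink_peak_amplitude <- function(evoked, times, labels,
                                 frontal = c("Fp1", "Fp2"),
                                 window_ms = c(-40, 40)) {
  rows <- match(frontal, labels)
  y <- colMeans(evoked[rows, , drop = FALSE])
  win <- times >= window_ms[1] & times <= window_ms[2]
  max(abs(y[win]))
}

# latency (column index) of the blink-locked peak of the mean frontal trace
blink_peak_index <- function(evoked, times, labels,
                             frontal = c("Fp1", "Fp2"),
                             window_ms = c(-40, 40)) {
  rows <- match(frontal, labels)
  y <- colMeans(evoked[rows, , drop = FALSE])
  win <- which(times >= window_ms[1] & times <= window_ms[2])
  win[which.max(abs(y[win]))]
}

# topography at the blink peak latency (one latency for all maps)
blink_topography <- function(evoked, times, labels, peak_index = NULL,
                             frontal = c("Fp1", "Fp2"),
                             window_ms = c(-40, 40)) {
  if (is.null(peak_index))
    peak_index <- blink_peak_index(evoked, times, labels, frontal,
                                   window_ms)
  evoked[, peak_index]
}

#' Score a correction run against a synthetic session
#'
#' Computes the session-level score card: blink-locked frontal peak
#' before/after and its reduction, blink-topography similarity
#' (uncorrected vs corrected), N1 amplitude and retention relative to the
#' injected value, VEP SNR before/after, and the decomposition count.
#'
#' @param session a [generate_session()] result.
#' @param corrected cleaned task data ([asr_clean()] output).
#' @param method label recorded in the score card.
#' @return one-row data.frame.
#' @export
score_correction <- function(session, corrected, method = "asr") {
  stopifnot(inherits(session, "synthetic_session"))
  raw <- session$task
  # baseline fully outside the ~[-250, 450] ms blink waveform support
  blink_w <- c(-400, 400)
  ep_raw <- epoch_data(raw, session$blink_times, blink_w, c(-400, -300))
  ep_cor <- epoch_data(corrected, session$blink_times, blink_w,
                       c(-400, -300))
  ev_raw <- evoked_mean(ep_raw)
  ev_cor <- evoked_mean(ep_cor)
  peak_raw <- blink_peak_amplitude(ev_raw, ep_raw$times, raw$labels)
  peak_cor <- blink_peak_amplitude(ev_cor, ep_cor$times, raw$labels)
  # both maps at the blink peak latency of the uncorrected average
  pk_idx <- blink_peak_index(ev_raw, ep_raw$times, raw$labels)
  topo_raw <- blink_topography(ev_raw, ep_raw$times, raw$labels, pk_idx)
  topo_cor <- blink_topography(ev_cor, ep_cor$times, raw$labels, pk_idx)
  sim <- topography_similarity(topo_raw, topo_cor)

  vp_raw <- epoch_data(raw, session$vep_times, c(-200, 500))
  vp_cor <- epoch_data(corrected, session$vep_times, c(-200, 500))
  evv_raw <- evoked_mean(vp_raw); rownames(evv_raw) <- raw$labels
  evv_cor <- evoked_mean(vp_cor); rownames(evv_cor) <- raw$labels
  n1_raw <- n1_amplitude(evv_raw, vp_raw$times)
  n1_cor <- n1_amplitude(evv_cor, vp_cor$times)
  snr_raw <- vep_snr(evv_raw, vp_raw$times, c("O1", "O2"))
  snr_cor <- vep_snr(evv_cor, vp_cor$times, c("O1", "O2"))

  ndec <- tryCatch(decomposition_counter(corrected),
                   error = function(e) NA_integer_)
  data.frame(
    method = method,
    blink_peak_raw_uv = peak_raw,
    blink_peak_corrected_uv = peak_cor,
    blink_reduction_pct = 100 * (1 - peak_cor / peak_raw),
    blink_topo_r2 = sim$r_squared,
    blink_topo_fisher_z = sim$fisher_z,
    n1_raw_uv = n1_raw$amplitude,
    n1_corrected_uv = n1_cor$amplitude,
    n1_injected_uv = session$config$n1_uV,
    n1_retention_pct = 100 * n1_cor$amplitude / session$config$n1_uV,
    snr_raw_db = snr_raw,
    snr_corrected_db = snr_cor,
    snr_drop_db = snr_raw - snr_cor,
    n_decompositions = ndec,
    stringsAsFactors = FALSE)
}

#' Write a score card as a tab-separated report
#'
#' @param scores data.frame (rows from [score_correction()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_card <- function(scores, path) {
  data.table::fwrite(scores, path, sep = "\t")
  invisible(path)
}
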