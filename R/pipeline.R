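# Pipeline driver: flatline detection -> drift removal -> subspace
# reconstruction, in that fixed order. Flat channels are excluded (removed
# from data and calibration) rather than interpolated; channel
# interpolation and correlation-based bad-channel rejection are out of
# scope of the online path.

#' Clean a recording end to end
#'
#' Runs the fixed stage order: flatline channel exclusion, drift removal
#' (on both the calibration stretch and the task data), model calibration
#' (optionally on self-cleaned calibration data), and ASR/rASR subspace
#' reconstruction.
#'
#' @param x task [eeg_segment()] to clean.
#' @param calib clean calibration [eeg_segment()] from the same montage.
#' @param params an [asr_params()] object.
#' @param clean_calibration clean the calibration stretch with the method
#'   itself before fitting the final model (default `TRUE`).
#' @param drift_removal apply the high-pass drift stage (default `TRUE`).
#' @return list with `data` (cleaned segment), `calibration` (the fitted
#'   model), `flat_channels` (labels excluded), `n_decompositions`.
#' @export
clean_artifacts <- function(x, calib, params = asr_params("asr"),
                            clean_calibration = TRUE,
                            drift_removal = TRUE) {
  stopifnot(inherits(x, "eeg_segment"), inherits(calib, "eeg_segment"))
  flat <- detect_flatlines(x, params$flatline)
  flat_labels <- x$labels[flat]
  if (any(flat)) {
    keep <- !flat
    x <- eeg_segment(x$data[keep, , drop = FALSE], x$srate,
                     x$labels[keep])
    ck <- match(x$labels, calib$labels)
    calib <- eeg_segment(calib$data[ck, , drop = FALSE], calib$srate,
                         x$labels)
  }
  if (drift_removal) {
    x <- remove_drifts(x, params$hp_band)
    calib <- remove_drifts(calib, params$hp_band)
  }
  cal <- if (clean_calibration) asr_calibrate_cleaned(calib, params)
         else asr_calibrate(calib, params)
  cleaned <- asr_clean(x, cal, params)
  list(data = cleaned, calibration = cal, flat_channels = flat_labels,
       n_decompositions = attr(cleaned, "n_decompositions"))
}
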