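# EEG container and plain-text recording I/O.
#
# Recordings are exchanged as a self-describing text container: '#'-prefixed
# header lines (srate, labels) followed by a tab-separated channels-in-columns
# numeric matrix. Event sidecars are two-column TSV (sample, type).

#' Construct an EEG segment
#'
#' A finite block of continuous multichannel EEG: a channels-by-samples
#' matrix in microvolts plus its sampling rate and channel labels.
#'
#' @param data channels-by-samples numeric matrix (µV).
#' @param srate sampling rate in Hz.
#' @param labels channel labels (10/20 names); defaults to rownames of
#'   `data` or `ch01`, `ch02`, ...
#' @return an object of class `eeg_segment` with fields `data`, `srate`,
#'   `labels`.
#' @export
eeg_segment <- function(data, srate, labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric channels-by-samples matrix")
  if (!all(is.finite(data)))
    stop("data must be finite")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("srate must be a positive scalar")
  if (nrow(data) < 2L)
    stop("need at least 2 channels")
  if (is.null(labels)) labels <- rownames(data)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("labels must match the number of channels")
  rownames(data) <- labels
  structure(list(data = data, srate = srate, labels = labels),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat("channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_segment <- function(x) dim(x$data)

n_samples <- function(x) ncol(x$data)
n_channels <- function(x) nrow(x$data)

#' Write an EEG segment to a plain-text container
#'
#' Header lines (`# srate:`, `# labels:`) followed by a tab-separated
#' samples-by-channels matrix (15 significant digits).
#'
#' @param x an [eeg_segment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(x, path) {
  stopifnot(inherits(x, "eeg_segment"))
  writeLines(c(sprintf("# srate: %.17g", x$srate),
               paste0("# labels: ", paste(x$labels, collapse = "\t"))),
             path)
  dt <- data.table::as.data.table(t(x$data))
  data.table::setnames(dt, x$labels)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     append = TRUE)
  invisible(path)
}

#' Read an EEG segment from a plain-text container
#'
#' @param path file written by [write_eeg()].
#' @return an [eeg_segment()].
#' @export
read_eeg <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (!startsWith(hdr[1L], "# srate:") || !startsWith(hdr[2L], "# labels:"))
    stop("malformed recording container: ", path)
  srate <- as.numeric(sub("# srate:", "", hdr[1L]))
  labels <- strsplit(sub("^# labels: ", "", hdr[2L]), "\t")[[1L]]
  dt <- data.table::fread(path, sep = "\t", skip = 2L, header = FALSE)
  X <- t(as.matrix(dt))
  eeg_segment(X, srate, labels)
}

#' Write an event table
#'
#' @param events data.frame with columns `sample` (1-based sample index)
#'   and `type` (character).
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("sample", "type") %in% names(events)))
  data.table::fwrite(events[, c("sample", "type")], path, sep = "\t")
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path TSV path with columns `sample`, `type`.
#' @return data.frame with columns `sample`, `type`.
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  as.data.frame(dt)
}

# slice a segment by sample indices, keeping metadata
segment_slice <- function(x, idx) {
  eeg_segment(x$data[, idx, drop = FALSE], x$srate, x$labels)
}

# horizontal concatenation of segments with identical montage
segment_cbind <- function(a, b) {
  stopifnot(identical(a$labels, b$labels), a$srate == b$srate)
  eeg_segment(cbind(a$data, b$data), a$srate, a$labels)
}
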