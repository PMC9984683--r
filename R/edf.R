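# Minimal European Data Format (EDF) I/O: 16-bit integer samples, physical
# dimension uV, one data record per second. Covers the subset of the format
# needed to exchange synthetic ICU-EEG recordings with standard viewers.

#' Write a recording to an EDF file
#'
#' @param rec a [recording()]; sample count must be a whole number of
#'   seconds (truncated otherwise).
#' @param path output file path.
#' @param patient_id,recording_id header identification strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "synthetic") {
  stopifnot(inherits(rec, "qeeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- nrow(rec$samples)
  n_rec <- ncol(rec$samples) %/% fs
  X <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(X, 1, min); pmax_ <- apply(X, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  dmin <- -32768; dmax <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad(patient_id, 80), pad(recording_id, 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + ns * 256, 8), pad("", 44),
    pad(n_rec, 8), pad("1", 8), pad(ns, 4)), con, eos = NULL)
  wf <- function(vals, w) writeChar(paste0(pad(vals, w), collapse = ""),
                                    con, eos = NULL)
  wf(rec$labels, 16)
  wf(rep("AgAgCl electrode", ns), 80)
  wf(rep("uV", ns), 8)
  wf(formatC(pmin_, format = "g", digits = 6), 8)
  wf(formatC(pmax_, format = "g", digits = 6), 8)
  wf(rep(dmin, ns), 8)
  wf(rep(dmax, ns), 8)
  wf(rep("", ns), 80)
  wf(rep(fs, ns), 8)
  wf(rep("", ns), 32)
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    D <- round((X[, idx, drop = FALSE] - pmin_) * gain + dmin)
    writeBin(as.integer(t(D)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports plain EDF with a uniform sampling rate across signals.
#'
#' @param path EDF file path.
#' @param t_start_h hours-after-trauma stamp to attach.
#' @return A [recording()].
#' @export
read_edf <- function(path, t_start_h = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  rc <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rc(8); rc(80); rc(80); rc(8); rc(8)
  rc(8)  # header bytes
  rc(44)
  n_rec <- as.integer(rc(8))
  dur <- as.numeric(rc(8))
  ns <- as.integer(rc(4))
  rf <- function(w) vapply(seq_len(ns), function(i) rc(w), character(1))
  labels <- rf(16)
  rf(80); rf(8)
  pmin_ <- as.numeric(rf(8)); pmax_ <- as.numeric(rf(8))
  dmin <- as.numeric(rf(8)); dmax <- as.numeric(rf(8))
  rf(80)
  spr <- as.integer(rf(8))
  rf(32)
  if (length(unique(spr)) != 1) stop("only uniform sampling rates supported")
  fs <- spr[1] / dur
  X <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    D <- matrix(readBin(con, integer(), n = ns * spr[1], size = 2,
                        endian = "little"), nrow = spr[1])
    X[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t((D - rep(dmin, each = spr[1])) /
          rep(dmax - dmin, each = spr[1]) *
          rep(pmax_ - pmin_, each = spr[1]) + rep(pmin_, each = spr[1]))
  }
  recording(X, labels, fs, t_start_h)
}
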