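#' Zero-phase Butterworth band-pass filter
#'
#' Applies the acquisition band-pass used for ICU EEG review: a sixth-order
#' Butterworth band-pass (0.1-40 Hz by default) with zero phase, i.e. the
#' effective magnitude response is the squared design response, as obtained
#' by forward-backward filtering. The filter is applied in the frequency
#' domain (squared magnitude of the digital Butterworth transfer function)
#' after reflection padding, which matches `signal::filtfilt` away from the
#' recording edges while filtering all channels in one FFT batch.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz.
#' @param order design order of the band-pass (6 = three pole pairs).
#' @return The filtered recording.
#' @export
bandpass <- function(rec, low = 0.1, high = 40, order = 6) {
  stopifnot(inherits(rec, "qeeg_recording"))
  if (rec$fs <= 2 * high) stop("sampling rate must exceed twice the upper edge")
  if (order %% 2 != 0) stop("band-pass design order must be even")
  # settling margin: three times the slow-edge time constant
  if (n_samples(rec) < 3 * rec$fs / low)
    stop("recording too short for stable zero-phase filtering at this high-pass edge")
  bf <- signal::butter(order / 2, c(low, high) / (rec$fs / 2), type = "pass")
  n <- n_samples(rec)
  # reflect-pad past the slow-edge settling time, rounded up so the padded
  # length has small prime factors (fast FFT)
  pad <- min(n, ceiling(3 * rec$fs / low))
  m <- stats::nextn(n + 2 * pad, c(2, 3, 5))
  pad_l <- pad + (m - n - 2 * pad) %/% 2
  pad_r <- m - n - pad_l
  X <- cbind(rec$samples[, pmin(pad_l:1, n), drop = FALSE],
             rec$samples,
             rec$samples[, pmax(n:(n - pad_r + 1), 1), drop = FALSE])
  z <- exp(-1i * 2 * pi * seq.int(0, m - 1) / m)
  H <- (outer(z, seq_along(bf$b) - 1, "^") %*% bf$b) /
       (outer(z, seq_along(bf$a) - 1, "^") %*% bf$a)
  G <- Mod(as.vector(H))^2
  Y <- Re(stats::mvfft(stats::mvfft(t(X)) * G, inverse = TRUE)) / m
  rec$samples <- t(Y)[, (pad_l + 1):(pad_l + n), drop = FALSE]
  rownames(rec$samples) <- rec$labels
  rec
}

#' Common average reference
#'
#' Re-references every sample to the instantaneous mean across channels, so
#' column means of the output are zero.
#'
#' @param rec a [recording()].
#' @return The re-referenced recording.
#' @export
common_average <- function(rec) {
  stopifnot(inherits(rec, "qeeg_recording"))
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec
}

#' Flat-channel detection
#'
#' A channel is flat when its amplitude variance over the analysis window is
#' at or below `var_thresh` (0.1 uV^2): disconnected or shorted electrodes.
#'
#' @param rec a [recording()].
#' @param var_thresh variance threshold in uV^2.
#' @return Named logical vector, `TRUE` for flat channels.
#' @export
detect_flat_channels <- function(rec, var_thresh = 0.1) {
  stopifnot(inherits(rec, "qeeg_recording"))
  v <- apply(rec$samples, 1, stats::var)
  stats::setNames(v <= var_thresh, rec$labels)
}

#' Threshold-based artifact detection
#'
#' Scans the common-average-referenced recording in non-overlapping windows
#' (10 s by default) and flags a (channel, window) cell when any sample
#' magnitude reaches `amp_thresh` (large peaks), or the window variance is at
#' or above `var_hi` (noise / muscle) or at or below `var_lo` (empty
#' channel). Flat channels have every window flagged.
#'
#' @param rec a [recording()], already common-average referenced.
#' @param window window length in seconds.
#' @param amp_thresh absolute amplitude threshold in uV.
#' @param var_hi,var_lo variance thresholds in uV^2.
#' @param flat_thresh whole-recording flat-channel variance threshold.
#' @return A list of class `qeeg_artifact_mask`: `window_flags`
#'   (windows x channels logical), `reasons` (same shape, character),
#'   `flat_channels` (logical per channel), `window_s`, `n_windows`.
#' @export
detect_artifacts <- function(rec, window = 10, amp_thresh = 200,
                             var_hi = 1400, var_lo = 1, flat_thresh = 0.1) {
  stopifnot(inherits(rec, "qeeg_recording"))
  wlen <- round(window * rec$fs)
  if (wlen > n_samples(rec)) stop("window longer than recording")
  nw <- n_samples(rec) %/% wlen
  nc <- n_channels(rec)
  flags <- matrix(FALSE, nw, nc, dimnames = list(NULL, rec$labels))
  reasons <- matrix(NA_character_, nw, nc, dimnames = list(NULL, rec$labels))
  for (ch in seq_len(nc)) {
    X <- matrix(rec$samples[ch, seq_len(nw * wlen)], nrow = wlen)
    amp <- colSums(abs(X) >= amp_thresh) > 0
    v <- (colSums(X^2) - colSums(X)^2 / wlen) / (wlen - 1)
    hi <- v >= var_hi
    lo <- v <= var_lo
    flags[, ch] <- amp | hi | lo
    reasons[amp, ch] <- "amplitude"
    reasons[!amp & hi, ch] <- "high_variance"
    reasons[!amp & !hi & lo, ch] <- "low_variance"
  }
  flat <- detect_flat_channels(rec, flat_thresh)
  if (any(flat)) {
    flags[, flat] <- TRUE
    reasons[, flat] <- "flat"
  }
  structure(list(window_flags = flags, reasons = reasons,
                 flat_channels = flat, window_s = window, n_windows = nw),
            class = "qeeg_artifact_mask")
}

#' Tabulate an artifact mask as a structured log
#'
#' @param mask a mask from [detect_artifacts()].
#' @return data.frame with columns channel, window_start_s, reason.
#' @export
artifact_log <- function(mask) {
  idx <- which(mask$window_flags, arr.ind = TRUE)
  data.frame(channel = colnames(mask$window_flags)[idx[, 2]],
             window_start_s = (idx[, 1] - 1) * mask$window_s,
             reason = mask$reasons[idx],
             stringsAsFactors = FALSE)[order(idx[, 2], idx[, 1]), ]
}

#' Extract three clean 10-minute segments around a clinical timepoint
#'
#' Takes the 30 minutes centred on `timepoint` hours after trauma, drops
#' flat channels, and splits the remainder into three contiguous 10-minute
#' segments. Artifact-flagged 10-s windows are carried along per channel so
#' that feature computation can exclude them.
#'
#' @param rec a preprocessed [recording()].
#' @param timepoint hours after trauma (12, 24, 48, 72 or 96 in the
#'   monitoring protocol).
#' @param mask artifact mask from [detect_artifacts()] on the same recording.
#' @param segment_min segment duration in minutes.
#' @return A list of class `qeeg_segment_set` with `segments` (each a list
#'   `samples`, `clean` windows x channels, `labels`, `fs`), `timepoint_h`,
#'   `channels`, and `available`. When every channel is flat the set is
#'   marked unavailable and `segments` is empty.
#' @export
extract_segments <- function(rec, timepoint, mask, segment_min = 10) {
  stopifnot(inherits(rec, "qeeg_recording"),
            inherits(mask, "qeeg_artifact_mask"))
  fs <- rec$fs
  seg_len <- round(segment_min * 60 * fs)
  half_span <- 1.5 * segment_min / 60  # hours
  start_h <- timepoint - half_span
  i0 <- round((start_h - rec$t_start_h) * 3600 * fs) + 1
  i1 <- i0 + 3 * seg_len - 1
  if (i0 < 1 || i1 > n_samples(rec))
    stop("recording does not cover the 30 minutes around the timepoint")
  keep <- !mask$flat_channels
  if (!any(keep)) {
    return(structure(list(segments = list(), timepoint_h = timepoint,
                          channels = character(0), available = FALSE),
                     class = "qeeg_segment_set"))
  }
  wlen <- round(mask$window_s * fs)
  segs <- lapply(0:2, function(s) {
    a <- i0 + s * seg_len
    idx <- a:(a + seg_len - 1)
    w0 <- (a - 1) %/% wlen  # first 10-s window covered by this segment
    nw <- seg_len %/% wlen
    wins <- w0 + seq_len(nw)
    wins <- pmin(wins, nrow(mask$window_flags))
    clean <- !mask$window_flags[wins, keep, drop = FALSE]
    list(samples = rec$samples[keep, idx, drop = FALSE],
         clean = clean, labels = rec$labels[keep], fs = fs)
  })
  structure(list(segments = segs, timepoint_h = timepoint,
                 channels = rec$labels[keep], available = TRUE),
            class = "qeeg_segment_set")
}

# Concatenate the clean 10-s windows of one channel of a segment.
# Used by time-domain features so that artifact windows never enter.
clean_signal <- function(seg, ch) {
  wlen <- ncol(seg$samples) %/% nrow(seg$clean)
  ok <- seg$clean[, ch]
  if (all(ok)) return(seg$samples[ch, ])
  idx <- unlist(lapply(which(ok), function(w) ((w - 1) * wlen + 1):(w * wlen)))
  seg$samples[ch, idx]
}
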