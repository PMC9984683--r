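#' Construct a multichannel EEG recording
#'
#' A `qeeg_recording` holds a channels-by-time matrix of scalp potentials in
#' microvolts together with 10-20 electrode labels, the sampling rate and the
#' time after trauma at which the recording starts.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param labels character vector of unique electrode labels, one per row.
#' @param fs sampling rate in Hz.
#' @param t_start_h hours after trauma of the first sample.
#' @return An object of class `qeeg_recording`.
#' @export
recording <- function(samples, labels, fs, t_start_h = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(labels) != nrow(samples))
    stop("one label per channel required")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  rownames(samples) <- labels
  structure(list(samples = samples, labels = as.character(labels),
                 fs = fs, t_start_h = t_start_h),
            class = "qeeg_recording")
}

#' @export
print.qeeg_recording <- function(x, ...) {
  cat(sprintf("<qeeg_recording> %d channels x %d samples (%.1f s @ %g Hz), start %.1f h after trauma\n",
              nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$fs, x$fs, x$t_start_h))
  invisible(x)
}

#' @export
dim.qeeg_recording <- function(x) dim(x$samples)

n_samples <- function(rec) ncol(rec$samples)
n_channels <- function(rec) nrow(rec$samples)
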