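# Welch power spectral density and Welch cross-spectral coherence.
#
# The `signal` package ships no pwelch/mscohere, and stats::spec.pgram
# smooths a single periodogram rather than averaging modified periodograms,
# so segment-averaged spectra are computed directly on stats::mvfft.

#' Welch power spectral density of a segment
#'
#' Averages modified periodograms over non-overlapping 10-s windows
#' (Hamming taper), per channel, giving a one-sided density in uV^2/Hz on a
#' 0.1-Hz grid. Windows flagged as artifact for a channel are excluded; a
#' channel with no clean window is returned as missing (NA row).
#'
#' @param seg one segment from [extract_segments()], or a plain
#'   channels x time matrix (then `fs` must be given and all windows are
#'   assumed clean).
#' @param fs sampling rate, only for matrix input.
#' @param window window length in seconds.
#' @return List of class `qeeg_spectrum`: `psd` (channels x freq, uV^2/Hz),
#'   `freqs` (Hz), `window_count` per channel, `labels`.
#' @export
welch_psd <- function(seg, fs = NULL, window = 10) {
  seg <- as_segment(seg, fs)
  fs <- seg$fs
  wlen <- round(window * fs)
  Tn <- ncol(seg$samples)
  if (Tn < 2 * wlen) stop("segment must cover at least two windows")
  nw <- Tn %/% wlen
  nc <- nrow(seg$samples)
  w <- hamming_window(wlen)
  U <- sum(w^2)
  nf <- wlen %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / wlen
  psd <- matrix(NA_real_, nc, nf, dimnames = list(seg$labels, NULL))
  counts <- integer(nc)
  # demean per window, taper, FFT all windows of all channels at once
  for (ch in seq_len(nc)) {
    ok <- which(seg$clean[seq_len(nw), ch])
    counts[ch] <- length(ok)
    if (length(ok) == 0) next
    X <- matrix(seg$samples[ch, seq_len(nw * wlen)], nrow = wlen)[, ok, drop = FALSE]
    X <- sweep(X, 2, colMeans(X)) * w
    P <- abs(stats::mvfft(X))^2 / (fs * U)
    P <- P[seq_len(nf), , drop = FALSE]
    P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]  # one-sided
    psd[ch, ] <- rowMeans(P)
  }
  structure(list(psd = psd, freqs = freqs, window_count = counts,
                 labels = seg$labels),
            class = "qeeg_spectrum")
}

#' Mean magnitude-squared coherence of a segment
#'
#' Welch cross-spectral estimate with a 4-s Hann window and 2-s overlap;
#' the magnitude-squared coherence |Sxy|^2/(Sxx Syy) is averaged over the
#' broadband analysis range and over all unordered channel pairs, giving a
#' value between 0 (no synchronization) and 1 (full synchronization).
#'
#' @inheritParams welch_psd
#' @param window,overlap Welch parameters in seconds.
#' @param range frequency range in Hz over which coherence is averaged.
#' @return Scalar mean coherence in `[0, 1]`.
#' @export
mean_coherence <- function(seg, fs = NULL, window = 4, overlap = 2,
                           range = analysis_range()) {
  seg <- as_segment(seg, fs)
  fs <- seg$fs
  nc <- nrow(seg$samples)
  if (nc < 2) return(NA_real_)
  wlen <- round(window * fs)
  step <- wlen - round(overlap * fs)
  starts <- seq(1, ncol(seg$samples) - wlen + 1, by = step)
  w <- hann_window(wlen)
  nf <- wlen %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / wlen
  fsel <- which(freqs >= range[1] & freqs <= range[2])
  nwin <- length(starts)
  # FFT of every tapered window for every channel: freq x channel x window
  Fw <- array(0 + 0i, c(length(fsel), nc, nwin))
  for (k in seq_along(starts)) {
    a <- starts[k]
    X <- t(seg$samples[, a:(a + wlen - 1), drop = FALSE])
    X <- sweep(X, 2, colMeans(X)) * w
    Fw[, , k] <- stats::mvfft(X)[fsel, , drop = FALSE]
  }
  msc_sum <- 0
  np <- nc * (nc - 1) / 2
  up <- upper.tri(matrix(0, nc, nc))
  for (f in seq_along(fsel)) {
    A <- matrix(Fw[f, , ], nc, nwin)
    S <- A %*% Conj(t(A))          # cross-spectral matrix at this frequency
    d <- Re(diag(S))
    msc_sum <- msc_sum + sum((abs(S)^2 / outer(d, d))[up])
  }
  msc_sum / (np * length(fsel))
}

as_segment <- function(seg, fs = NULL) {
  if (is.list(seg) && !is.null(seg$samples)) return(seg)
  seg <- as.matrix(seg)
  if (is.null(fs)) stop("fs required for matrix input")
  nw <- max(1L, ncol(seg) %/% round(10 * fs))
  list(samples = seg, clean = matrix(TRUE, nw, nrow(seg)),
       labels = rownames(seg) %||% paste0("ch", seq_len(nrow(seg))),
       fs = fs)
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

`%||%` <- function(a, b) if (is.null(a)) b else a
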