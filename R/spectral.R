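#' Band powers from a Welch spectrum
#'
#' Integrates the per-channel PSD over the broadband analysis range (total
#' power) and within each classical band (absolute power); relative power is
#' the ratio of band to total power. Per-channel values are averaged across
#' channels with a valid spectrum. Band edges follow the clinical scheme in
#' [band_scheme()]; the alpha and beta bands deliberately overlap.
#'
#' @param spec a `qeeg_spectrum` from [welch_psd()].
#' @param bands band scheme, named list of c(low, high) Hz.
#' @param range broadband range for total power.
#' @return List with `total_power` (uV^2), `abs_power`, `rel_power`
#'   (named per band); degenerate zero-power input yields NA relative power.
#' @export
band_powers <- function(spec, bands = band_scheme(), range = analysis_range()) {
  df <- spec$freqs[2] - spec$freqs[1]
  ok <- stats::complete.cases(spec$psd)
  if (!any(ok)) return(list(total_power = NA_real_,
                            abs_power = nab(bands), rel_power = nab(bands)))
  P <- spec$psd[ok, , drop = FALSE]
  tot_ch <- rowSums(P[, band_bins(spec$freqs, range), drop = FALSE]) * df
  abs_ch <- vapply(bands, function(b)
    rowSums(P[, band_bins(spec$freqs, b), drop = FALSE]) * df,
    numeric(nrow(P)))
  abs_ch <- matrix(abs_ch, nrow = nrow(P), dimnames = list(NULL, names(bands)))
  total <- mean(tot_ch)
  rel <- if (total > 0) colMeans(abs_ch / tot_ch) else nab(bands)
  list(total_power = total,
       abs_power = colMeans(abs_ch),
       rel_power = rel)
}

band_bins <- function(freqs, b) which(freqs >= b[1] & freqs < b[2])
nab <- function(bands) stats::setNames(rep(NA_real_, length(bands)), names(bands))

#' Normalized alpha/delta ratio
#'
#' The contrast (alpha - delta)/(alpha + delta), in `[-1, 1]`: positive when
#' alpha power dominates, negative under EEG slowing.
#'
#' @param abs_power named band powers (needs `alpha` and `delta`).
#' @export
alpha_delta_ratio <- function(abs_power) {
  a <- abs_power[["alpha"]]; d <- abs_power[["delta"]]
  if (!is.finite(a) || !is.finite(d) || a + d <= 0) return(NA_real_)
  (a - d) / (a + d)
}

#' Spectral edge frequency (90%)
#'
#' Smallest grid frequency below which at least 90% of the total power in
#' the analysis range lies, channel-averaged.
#'
#' @inheritParams band_powers
#' @param q edge quantile (0.9).
#' @export
sef90 <- function(spec, q = 0.9, range = analysis_range()) {
  ok <- stats::complete.cases(spec$psd)
  if (!any(ok)) return(NA_real_)
  sel <- band_bins_closed(spec$freqs, range)
  f <- spec$freqs[sel]
  edge <- apply(spec$psd[ok, sel, drop = FALSE], 1, function(p) {
    s <- sum(p)
    if (s <= 0) return(NA_real_)
    f[which(cumsum(p) >= q * s)[1]]
  })
  mean(edge, na.rm = TRUE)
}

band_bins_closed <- function(freqs, b) which(freqs >= b[1] & freqs <= b[2])

#' Band-power variability over time
#'
#' Band power is computed per clean 10-s window, forming a time series per
#' channel; variability is the ratio of the median absolute deviation to the
#' median of that series (unitless, scale-invariant), channel-averaged.
#'
#' @inheritParams welch_psd
#' @param band c(low, high) Hz.
#' @param min_windows minimum clean windows required per channel.
#' @export
variability <- function(seg, band, fs = NULL, window = 10, min_windows = 5) {
  seg <- as_segment(seg, fs)
  fs <- seg$fs
  wlen <- round(window * fs)
  nw <- ncol(seg$samples) %/% wlen
  w <- hamming_window(wlen)
  U <- sum(w^2)
  nf <- wlen %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / wlen
  bsel <- band_bins(freqs, band)
  df <- fs / wlen
  vals <- vapply(seq_len(nrow(seg$samples)), function(ch) {
    ok <- which(seg$clean[seq_len(nw), ch])
    if (length(ok) < min_windows) return(NA_real_)
    X <- matrix(seg$samples[ch, seq_len(nw * wlen)], nrow = wlen)[, ok, drop = FALSE]
    X <- sweep(X, 2, colMeans(X)) * w
    P <- abs(stats::mvfft(X))^2 / (fs * U)
    P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]
    bp <- colSums(P[bsel, , drop = FALSE]) * df  # band power per window
    med <- stats::median(bp)
    if (med <= 0) return(NA_real_)
    stats::mad(bp, constant = 1) / med
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Pairwise-derived brain symmetry index
#'
#' For each homologous left/right electrode pair and each frequency bin in
#' 0.5-20 Hz, the normalized power difference |(R - L)/(R + L)| is computed
#' from the Welch spectra; the BSI is the mean over pairs and bins, 0 for a
#' perfectly symmetric recording and 1 when one hemisphere is silent.
#'
#' @inheritParams band_powers
#' @param pairs two-column matrix of homologous (left, right) labels.
#' @param range frequency range in Hz.
#' @return Scalar in `[0, 1]`, or NA when no homologous pair is present.
#' @export
bsi <- function(spec, pairs = homologous_pairs(), range = c(0.5, 20)) {
  sel <- band_bins_closed(spec$freqs, range)
  have <- pairs[, 1] %in% spec$labels & pairs[, 2] %in% spec$labels
  pairs <- pairs[have, , drop = FALSE]
  vals <- c()
  for (k in seq_len(nrow(pairs))) {
    L <- spec$psd[pairs[k, 1], sel]
    R <- spec$psd[pairs[k, 2], sel]
    if (anyNA(L) || anyNA(R)) next
    s <- L + R
    d <- abs(R - L) / s
    d[s == 0] <- 0  # no power on either side: symmetric by convention
    vals <- c(vals, mean(d))
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Spectral Shannon entropy
#'
#' Shannon entropy (bits) of the Welch PSD normalized to a probability
#' distribution over frequency bins in the analysis range; higher entropy
#' corresponds to a flatter spectrum and a less predictable signal.
#' Channel-averaged.
#'
#' @inheritParams band_powers
#' @export
shannon_entropy <- function(spec, range = analysis_range()) {
  sel <- band_bins_closed(spec$freqs, range)
  ok <- stats::complete.cases(spec$psd)
  if (!any(ok)) return(NA_real_)
  ent <- apply(spec$psd[ok, sel, drop = FALSE], 1, function(p) {
    s <- sum(p)
    if (s <= 0) return(NA_real_)
    q <- p[p > 0] / s
    -sum(q * log2(q))
  })
  mean(ent, na.rm = TRUE)
}

#' Amplitude regularity
#'
#' Continuity measure based on the variance of the signal amplitude: the
#' squared signal is smoothed with a 0.5-s moving average, sorted in
#' descending order into q(1..N), and the statistic
#' sqrt(3 * sum(i^2 q_i) / (N^2 * sum(q_i))) is returned, clipped to
#' `[0, 1]`. A constant-amplitude signal approaches 1; isolated bursts in a
#' suppressed background give values near 0. Channel-averaged over clean
#' data.
#'
#' @inheritParams welch_psd
#' @param smooth_s moving-average length in seconds.
#' @export
regularity <- function(seg, fs = NULL, smooth_s = 0.5) {
  seg <- as_segment(seg, fs)
  fs <- seg$fs
  k <- max(1L, round(smooth_s * fs))
  vals <- vapply(seq_len(nrow(seg$samples)), function(ch) {
    x <- clean_signal(seg, ch)
    if (length(x) < 2 * k) return(NA_real_)
    sq <- running_mean(x^2, k)
    q <- sort(sq, decreasing = TRUE)
    N <- length(q)
    S <- sum(q)
    if (S <= 0) return(NA_real_)
    min(1, sqrt(3 * sum(seq_len(N)^2 * q) / (N^2 * S)) )
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

# centred running mean over k samples (interior points only)
running_mean <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k
}
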