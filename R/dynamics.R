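#' Aperiodic (1/f) spectral fit
#'
#' Parameterizes the aperiodic component of the power spectrum: a robust
#' straight-line fit of log10 PSD against log10 frequency over 1-40 Hz with
#' iterative masking of periodic peaks (bins more than 2.5 residual SD above
#' the fit are dropped and the line refit, up to 3 iterations). The offset
#' is the intercept (log10 uV^2/Hz at 1 Hz) and the exponent alpha is minus
#' the slope of the 1/f^alpha component. Channel-averaged.
#'
#' @param spec a `qeeg_spectrum` from [welch_psd()].
#' @param range fit range in Hz.
#' @param sd_thresh peak-masking threshold in residual SDs.
#' @param max_iter masking iterations.
#' @return List of class `qeeg_aperiodic`: `offset`, `exponent`, `fit_range`,
#'   `r2`, plus per-channel values.
#' @export
fit_aperiodic <- function(spec, range = c(1, 40), sd_thresh = 2.5,
                          max_iter = 3) {
  sel <- band_bins_closed(spec$freqs, range)
  if (length(sel) < 20) stop("need at least 20 frequency bins in fit range")
  per_ch <- t(apply(spec$psd, 1, function(p) {
    y <- p[sel]; f <- spec$freqs[sel]
    pos <- is.finite(y) & y > 0
    if (sum(pos) < 20) return(c(NA_real_, NA_real_, NA_real_))
    ly <- log10(y[pos]); lf <- log10(f[pos])
    keep <- rep(TRUE, length(ly))
    for (it in 0:max_iter) {
      fit <- stats::lm.fit(cbind(1, lf[keep]), ly[keep])
      if (it == max_iter) break
      pred <- fit$coefficients[1] + fit$coefficients[2] * lf
      s <- stats::sd(ly[keep] - pred[keep])
      if (s == 0) break
      newkeep <- ly <= pred + sd_thresh * s
      if (all(newkeep == keep)) break
      keep <- newkeep
      if (sum(keep) < 10) break
    }
    r2 <- 1 - sum(fit$residuals^2) / sum((ly[keep] - mean(ly[keep]))^2)
    c(fit$coefficients[1], -fit$coefficients[2], r2)
  }))
  colnames(per_ch) <- c("offset", "exponent", "r2")
  structure(list(offset = mean(per_ch[, "offset"], na.rm = TRUE),
                 exponent = mean(per_ch[, "exponent"], na.rm = TRUE),
                 fit_range = range,
                 r2 = mean(per_ch[, "r2"], na.rm = TRUE),
                 per_channel = per_ch),
            class = "qeeg_aperiodic")
}

#' Band-limited analytic signal
#'
#' Zero-phase band-pass filters each channel (4th-order Butterworth) and
#' extracts the analytic signal via the Hilbert transform (frequency-domain
#' construction): the envelope is the magnitude, the instantaneous phase the
#' angle.
#'
#' @inheritParams welch_psd
#' @param band c(low, high) Hz.
#' @return List `envelope`, `phase` (channels x time matrices).
#' @export
band_analytic <- function(seg, band, fs = NULL) {
  seg <- as_segment(seg, fs)
  A <- band_analytic_matrix(seg$samples, band, seg$fs)
  list(envelope = Mod(A), phase = Arg(A), labels = seg$labels, fs = seg$fs)
}

# Zero-phase band filtering and analytic-signal construction in one FFT
# pass: the squared magnitude response of a 4th-order Butterworth band-pass
# (the zero-phase forward-backward response) is applied to the one-sided
# spectrum of every channel; the inverse transform is the analytic signal
# of the band-filtered data. Returns channels x time complex matrix.
band_analytic_matrix <- function(X, band, fs, order = 4) {
  n <- ncol(X)
  Xf <- stats::mvfft(t(X))
  f <- c(0, seq_len(n - 1)) * fs / n
  pos <- f <= fs / 2
  f <- pmin(f, fs - f)
  g <- butter_zerophase_gain(f, band, order)
  h <- ifelse(pos, 2, 0)  # one-sided doubling; negative frequencies dropped
  h[1] <- 1
  if (n %% 2 == 0) h[n / 2 + 1] <- 1
  t(stats::mvfft(Xf * (g * h), inverse = TRUE)) / n
}

# As band_analytic_matrix, but for several bands off one shared forward
# FFT, returning analytic signals decimated by `dec` (the bands all lie
# well below the decimated Nyquist, so decimation is exact up to the
# filter's stop-band leakage). Used by the feature-extraction fast path.
band_analytic_multi <- function(X, bands, fs, order = 4, dec = 4L) {
  n <- ncol(X)
  m <- n %/% dec
  Xf <- stats::mvfft(t(X))
  f <- c(0, seq_len(n - 1)) * fs / n
  pos <- f <= fs / 2
  f <- pmin(f, fs - f)
  h <- ifelse(pos, 2, 0)
  h[1] <- 1
  lapply(bands, function(band) {
    g <- butter_zerophase_gain(f[seq_len(m)], band, order) * h[seq_len(m)]
    t(stats::mvfft(Xf[seq_len(m), , drop = FALSE] * g, inverse = TRUE)) / n
  })
}

# |H(f)|^2 of an analog Butterworth band-pass of the given (even) order:
# the effective gain of one forward and one backward pass.
butter_zerophase_gain <- function(f, band, order = 4) {
  f0 <- sqrt(band[1] * band[2])
  Q <- f0 / (band[2] - band[1])
  x <- ifelse(f > 0, Q * (f / f0 - f0 / f), Inf)
  (1 / (1 + x^order))^2
}

# analytic signal via one-sided spectrum (x + i * Hilbert(x))
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Kuramoto order parameter
#'
#' Global phase synchrony over channels: R(t) = |mean over channels of
#' exp(i phase)|, between 0 (phases uniformly spread) and 1 (full
#' synchrony).
#'
#' @param phases channels x time matrix of instantaneous phases (radians).
#' @return Numeric vector R(t) in `[0, 1]`.
#' @export
kuramoto_order <- function(phases) {
  Mod(colMeans(exp(1i * phases)))
}

#' Long-range temporal correlations of the amplitude envelope
#'
#' The channel-summed band envelope from [band_analytic()] is fed to [dfa()]
#' with the smallest window equal to one oscillation period of the band
#' (geometric-mean frequency) and the largest one fourth of the segment.
#'
#' @inheritParams band_analytic
#' @return `qeeg_dfa` result; `hurst` is NA with low `fit_r2` flagged when
#'   the envelope is degenerate (near-constant).
#' @export
lrtc_amplitude <- function(seg, band, fs = NULL) {
  seg <- as_segment(seg, fs)
  an <- band_analytic(seg, band)
  series <- colSums(an$envelope)
  lrtc_dfa(series, band, seg$fs)
}

#' Long-range temporal correlations of global phase dynamics
#'
#' [dfa()] applied to the Kuramoto order parameter time course of the band,
#' with the same window rule as [lrtc_amplitude()].
#'
#' @inheritParams band_analytic
#' @export
lrtc_phase <- function(seg, band, fs = NULL) {
  seg <- as_segment(seg, fs)
  an <- band_analytic(seg, band)
  series <- kuramoto_order(an$phase)
  lrtc_dfa(series, band, seg$fs)
}

lrtc_dfa <- function(series, band, fs) {
  if (stats::sd(series) < .Machine$double.eps^0.5 * (abs(mean(series)) + 1)) {
    res <- dfa_missing()
    res$fit_r2 <- 0
    return(res)
  }
  f0 <- sqrt(band[1] * band[2])  # geometric-mean frequency of the band
  n_min <- max(8, round(fs / f0))
  dfa(series, n_min = n_min, n_max = floor(length(series) / 4))
}

#' Two-dimensional brain-state trajectory
#'
#' Band-pass filters the segment and projects the channels x time data onto
#' its first two principal components (eigenvectors of the channel
#' covariance), each projection standardized. Component signs are fixed by
#' forcing a positive loading sum, so trajectories are reproducible.
#'
#' @inheritParams band_analytic
#' @return 2 x time matrix (rows PC1, PC2) with attribute `var_explained`.
#' @export
pc_trajectory <- function(seg, band, fs = NULL) {
  seg <- as_segment(seg, fs)
  X <- Re(band_analytic_matrix(seg$samples, band, seg$fs))
  pc_project(X)
}

#' Broken detailed balance of a 2-D state trajectory
#'
#' Discretizes each principal-component axis into equal-occupancy bins
#' (3 per axis, 9 states) and estimates the joint frequency F[i, j] of
#' consecutive states (lag 1 sample). Detailed balance holds when F is
#' symmetric; its violation is quantified by the entropy production
#' \deqn{EP = \tfrac12 \sum_{i \ne j} (F_{ij} - F_{ji})\,\ln(F_{ij}/F_{ji})}
#' (pairs with a zero count in either direction are skipped), and by the
#' flux curl: the net clockwise-minus-counterclockwise probability
#' circulation summed over the four elementary plaquettes of the 3 x 3 grid.
#'
#' @param trajectory 2 x time matrix from [pc_trajectory()], or any 2-row
#'   numeric matrix.
#' @param n_bins bins per axis.
#' @param lag transition lag in samples.
#' @return List of class `qeeg_transition`: `joint_freq` (9 x 9, sums to 1),
#'   `entropy_production` (nats/step, >= 0), `flux_curl`, `state_grid`.
#' @export
transition_model <- function(trajectory, n_bins = 3, lag = 1) {
  stopifnot(nrow(trajectory) == 2)
  Tn <- ncol(trajectory)
  if (Tn < 100 * lag) {
    return(structure(list(joint_freq = NULL, entropy_production = NA_real_,
                          flux_curl = NA_real_, state_grid = NULL),
                     class = "qeeg_transition"))
  }
  bx <- equal_occupancy_bins(trajectory[1, ], n_bins)
  by <- equal_occupancy_bins(trajectory[2, ], n_bins)
  state <- (by - 1) * n_bins + bx  # column-major over the grid
  s0 <- state[seq_len(Tn - lag)]
  s1 <- state[seq_len(Tn - lag) + lag]
  ns <- n_bins^2
  F <- table(factor(s0, levels = 1:ns), factor(s1, levels = 1:ns))
  F <- unclass(F) / length(s0)
  structure(list(joint_freq = F,
                 entropy_production = entropy_production(F),
                 flux_curl = flux_curl(F, n_bins),
                 state_grid = n_bins),
            class = "qeeg_transition")
}

equal_occupancy_bins <- function(x, n_bins) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  br <- unique(qs[-c(1, n_bins + 1)])  # interior tertile boundaries
  findInterval(x, br, left.open = TRUE) + 1L
}

#' @rdname transition_model
#' @param F joint transition frequency matrix (sums to 1).
#' @export
entropy_production <- function(F) {
  ep <- 0
  n <- nrow(F)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (F[i, j] > 0 && F[j, i] > 0)
      ep <- ep + (F[i, j] - F[j, i]) * log(F[i, j] / F[j, i])
  }
  ep  # the half in the pairwise sum cancels against counting each pair once
}

#' @rdname transition_model
#' @param n_bins grid size per axis.
#' @export
flux_curl <- function(F, n_bins = 3) {
  net <- F - t(F)  # net probability flow i -> j
  state_id <- function(ix, iy) (iy - 1) * n_bins + ix
  total <- 0
  for (px in seq_len(n_bins - 1)) for (py in seq_len(n_bins - 1)) {
    # plaquette corners, clockwise starting bottom-left:
    # (px,py) -> (px,py+1) -> (px+1,py+1) -> (px+1,py) -> (px,py)
    cyc <- c(state_id(px, py), state_id(px, py + 1),
             state_id(px + 1, py + 1), state_id(px + 1, py),
             state_id(px, py))
    for (k in 1:4) total <- total + net[cyc[k], cyc[k + 1]]
  }
  total
}
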