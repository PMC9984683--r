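#' Detrended fluctuation analysis
#'
#' Estimates the Hurst exponent of a time series from the scaling of
#' detrended fluctuations of its cumulative sum. The series is demeaned and
#' integrated; for each of ~15 logarithmically spaced window sizes the
#' profile is split into non-overlapping windows, a least-squares line is
#' removed from each window, and the fluctuation F(n) is the root mean
#' square residual pooled over windows. The Hurst exponent is the slope of
#' log F(n) versus log n. H = 0.5 corresponds to an uncorrelated
#' (memoryless) process; H > 0.5 indicates long-range temporal correlations.
#'
#' @param series numeric vector.
#' @param n_min smallest window size in samples (default 16).
#' @param n_max largest window size in samples (default `length(series)/4`).
#' @param n_sizes number of log-spaced window sizes (default 15).
#' @return A list of class `qeeg_dfa` with elements `hurst`, `window_sizes`,
#'   `fluctuations`, and `fit_r2` (r-squared of the log-log fit).
#' @examples
#' dfa(rnorm(4096))$hurst  # close to 0.5
#' @export
dfa <- function(series, n_min = 16, n_max = floor(length(series) / 4),
                n_sizes = 15) {
  series <- as.numeric(series)
  N <- length(series)
  if (n_min < 4) stop("n_min must be at least 4")
  if (N < 4 * n_min) stop("series too short for requested n_min")
  n_max <- min(n_max, floor(N / 4))
  sizes <- unique(round(exp(seq(log(n_min), log(n_max), length.out = n_sizes))))
  sizes <- sizes[sizes >= n_min & sizes <= n_max]
  if (length(sizes) < 4) return(dfa_missing())
  prof <- cumsum(series - mean(series))
  F <- vapply(sizes, function(n) dfa_fluct(prof, n), numeric(1))
  keep <- is.finite(F) & F > 0
  if (sum(keep) < 4) return(dfa_missing())
  fit <- stats::lm.fit(cbind(1, log(sizes[keep])), log(F[keep]))
  r2 <- 1 - sum(fit$residuals^2) /
    sum((log(F[keep]) - mean(log(F[keep])))^2)
  structure(list(hurst = unname(fit$coefficients[2]),
                 window_sizes = sizes, fluctuations = F, fit_r2 = r2),
            class = "qeeg_dfa")
}

dfa_missing <- function() {
  structure(list(hurst = NA_real_, window_sizes = integer(0),
                 fluctuations = numeric(0), fit_r2 = NA_real_),
            class = "qeeg_dfa")
}

# RMS residual of per-window linear detrending at window size n,
# vectorized over all non-overlapping windows at once.
dfa_fluct <- function(prof, n) {
  k <- length(prof) %/% n
  Y <- matrix(prof[seq_len(k * n)], nrow = n)
  t <- seq_len(n)
  tc <- t - mean(t)
  # per-window OLS line: intercept = column mean, slope = <tc, y>/<tc, tc>
  mu <- colMeans(Y)
  slope <- crossprod(tc, Y)[1, ] / sum(tc^2)
  resid <- Y - rep(mu, each = n) - outer(tc, slope)
  sqrt(mean(resid^2))
}
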