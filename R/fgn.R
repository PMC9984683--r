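#' Generate fractional Gaussian noise
#'
#' Exact synthesis of a stationary fractional Gaussian noise (fGn) series by
#' circulant embedding (Davies-Harte): the target autocovariance
#' \deqn{\gamma(k) = \tfrac{1}{2}(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}
#' is embedded in a circulant matrix whose eigenvalues are obtained by FFT;
#' a complex Gaussian vector weighted by the square-root eigenvalues is then
#' transformed back. The result has unit variance and Hurst exponent `h`,
#' so it serves as ground truth for detrended fluctuation analysis: `h = 0.5`
#' is white noise, `h > 0.5` long-range persistent, `h < 0.5` antipersistent.
#'
#' @param h Hurst exponent, strictly between 0 and 1.
#' @param n number of samples.
#' @param seed optional integer seed (local to this call).
#' @return Numeric vector of length `n` with (population) unit variance.
#' @examples
#' x <- generate_fgn(0.8, 4096, seed = 1)
#' @export
generate_fgn <- function(h, n, seed = NULL) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0 || h >= 1)
    stop("h must lie strictly in (0, 1)")
  if (n < 2) stop("n must be at least 2")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  k <- 0:(n - 1)
  gam <- 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
  # first row of the 2n-point circulant embedding
  row <- c(gam, 0, rev(gam[-1]))
  lam <- Re(stats::fft(row))
  lam[lam < 0] <- 0  # clip tiny negative eigenvalues from roundoff
  m <- 2 * n
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  x <- Re(stats::fft(sqrt(lam / (2 * m)) * z, inverse = FALSE))
  # real and imaginary parts are two independent draws; take the real part
  x[seq_len(n)] * sqrt(2)
}
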