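power_law_spectrum <- function(offset, exponent, fs = 256, wlen = 2560,
                               n_ch = 2) {
  nf <- wlen %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / wlen
  psd <- matrix(rep(ifelse(freqs > 0, 10^offset / pmax(freqs, 1e-12)^exponent, 0),
                    each = n_ch), n_ch)
  structure(list(psd = psd, freqs = freqs,
                 window_count = rep(1L, n_ch),
                 labels = paste0("ch", seq_len(n_ch))),
            class = "qeeg_spectrum")
}

test_that("aperiodic fit recovers a noiseless power law to machine precision", {
  for (a in c(0.8, 1.5, 2.3)) {
    fit <- fit_aperiodic(power_law_spectrum(offset = 1.2, exponent = a))
    expect_equal(fit$exponent, a, tolerance = 1e-9)
    expect_equal(fit$offset, 1.2, tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
})

test_that("peak masking keeps the exponent accurate under an alpha peak", {
  spec <- power_law_spectrum(offset = 1, exponent = 1.5)
  peak <- 8 * exp(-(spec$freqs - 10)^2 / (2 * 1.5^2))
  spec$psd <- spec$psd + rep(peak, each = nrow(spec$psd))
  fit <- fit_aperiodic(spec)
  expect_equal(fit$exponent, 1.5, tolerance = 0.1)
  # without masking the peak biases the fit far more
  fit0 <- fit_aperiodic(spec, sd_thresh = Inf)
  expect_gt(abs(fit0$exponent - 1.5), abs(fit$exponent - 1.5))
})

test_that("the analytic signal has the textbook envelope and phase for a tone", {
  fs <- 128
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- 3 * cos(2 * pi * 10 * t)
  a <- analytic_signal(x)
  expect_equal(Re(a), x, tolerance = 1e-9)
  expect_equal(Mod(a), rep(3, length(x)), tolerance = 1e-6)
  dphi <- diff(Arg(a)) %% (2 * pi)
  expect_equal(stats::median(dphi), 2 * pi * 10 / fs, tolerance = 1e-6)
})

test_that("band-limited analytic signal isolates in-band content", {
  fs <- 128
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- matrix(2 * sin(2 * pi * 10 * t) + 2 * sin(2 * pi * 2 * t), 1)
  alpha <- band_analytic(x, band = c(8, 13), fs = fs)
  delta <- band_analytic(x, band = c(0.5, 4), fs = fs)
  i <- (10 * fs):(110 * fs)
  expect_equal(mean(alpha$envelope[1, i]), 2, tolerance = 0.05)
  expect_equal(mean(delta$envelope[1, i]), 2, tolerance = 0.05)
  # alpha phase advances at ~10 Hz, delta at ~2 Hz
  f_alpha <- stats::median(diff(alpha$phase[1, i]) %% (2 * pi)) * fs / (2 * pi)
  expect_equal(f_alpha, 10, tolerance = 0.05)
})

test_that("Kuramoto order parameter hits both endpoints", {
  ph <- matrix(rep(seq(0, 10, length.out = 500), each = 4), 4)
  expect_equal(kuramoto_order(ph), rep(1, 500), tolerance = 1e-12)
  spread <- matrix(2 * pi * (0:7) / 8, 8, 100)
  expect_equal(kuramoto_order(spread), rep(0, 100), tolerance = 1e-12)
})

test_that("amplitude and phase LRTC pipelines return sane Hurst estimates", {
  set.seed(30)
  fs <- 128
  X <- matrix(rnorm(4 * 600 * fs), 4)
  h_amp <- lrtc_amplitude(X, band = c(8, 13), fs = fs)
  expect_s3_class(h_amp, "qeeg_dfa")
  expect_true(is.finite(h_amp$hurst))
  # band-limited envelopes are smooth below one oscillation cycle, so the
  # estimate is upward-biased for white noise; it must still be a valid
  # scaling exponent
  expect_gt(h_amp$hurst, 0.3)
  expect_lt(h_amp$hurst, 1.1)
  expect_gt(h_amp$fit_r2, 0.9)
  h_ph <- lrtc_phase(X, band = c(8, 13), fs = fs)
  expect_true(is.finite(h_ph$hurst))
  # degenerate constant series is flagged, not guessed
  flat <- lrtc_dfa(rep(1, 10000), c(8, 13), fs)
  expect_true(is.na(flat$hurst))
  expect_identical(flat$fit_r2, 0)
})

test_that("PC trajectory is standardized, ordered and sign-stable", {
  set.seed(31)
  fs <- 128
  X <- matrix(rnorm(6 * 300 * fs), 6)
  X[1:3, ] <- X[1:3, ] + rep(10 * sin(2 * pi * 10 * seq_len(ncol(X)) / fs),
                             each = 3)
  tr <- pc_trajectory(X, band = c(8, 13), fs = fs)
  expect_equal(dim(tr), c(2, ncol(X)))
  expect_equal(unname(apply(tr, 1, stats::sd)), c(1, 1), tolerance = 1e-9)
  ve <- attr(tr, "var_explained")
  expect_gte(ve[1], ve[2])
  expect_gt(ve[1], 0.5)  # the planted shared component dominates
  # deterministic sign convention: recomputation is identical
  expect_identical(tr, pc_trajectory(X, band = c(8, 13), fs = fs))
})

test_that("equal-occupancy binning balances occupancy", {
  set.seed(32)
  x <- rnorm(9000)
  b <- qeegtbi:::equal_occupancy_bins(x, 3)
  expect_setequal(unique(b), 1:3)
  expect_equal(as.numeric(table(b)), rep(3000, 3), tolerance = 0.01)
  # heavily tied input still returns valid bins
  b2 <- qeegtbi:::equal_occupancy_bins(rep(c(0, 1), 500), 3)
  expect_true(all(b2 %in% 1:3))
})

test_that("entropy production matches the closed-form two-state oracle", {
  F <- matrix(0, 2, 2)
  F[1, 2] <- 0.4; F[2, 1] <- 0.1; F[1, 1] <- 0.3; F[2, 2] <- 0.2
  expect_equal(entropy_production(F), 0.3 * log(4))
  # symmetric tables produce exactly zero
  S <- matrix(1 / 16, 4, 4)
  expect_identical(entropy_production(S), 0)
  expect_identical(flux_curl(matrix(1 / 81, 9, 9), 3), 0)
})

test_that("transition model detects rotation and its time reversal", {
  set.seed(33)
  n <- 20000
  th <- cumsum(rep(0.15, n)) + rnorm(n, sd = 0.05)
  traj <- rbind(cos(th), sin(th)) + matrix(rnorm(2 * n, sd = 0.05), 2)
  tm <- transition_model(traj)
  expect_s3_class(tm, "qeeg_transition")
  expect_equal(sum(tm$joint_freq), 1, tolerance = 1e-12)
  expect_gt(tm$entropy_production, 0.1)
  expect_gt(abs(tm$flux_curl), 0.01)
  tm_rev <- transition_model(traj[, n:1])
  # time reversal flips the circulation and preserves entropy production
  expect_equal(tm_rev$flux_curl, -tm$flux_curl, tolerance = 1e-9)
  expect_equal(tm_rev$entropy_production, tm$entropy_production,
               tolerance = 1e-9)
})

test_that("a reversible trajectory has near-zero entropy production", {
  set.seed(34)
  traj <- matrix(rnorm(2 * 50000), 2)
  tm <- transition_model(traj)
  expect_lt(tm$entropy_production, 0.01)
  expect_lt(abs(tm$flux_curl), 0.02)
})

test_that("short trajectories yield NA transition statistics", {
  tm <- transition_model(matrix(rnorm(2 * 50), 2))
  expect_true(is.na(tm$entropy_production))
  expect_true(is.na(tm$flux_curl))
})
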