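#' Synthetic ICU-EEG generation profile
#'
#' Collects the generative targets for one synthetic scalp EEG recording:
#' the aperiodic 1/f background (offset in log10 uV^2/Hz at 1 Hz, exponent
#' alpha), band-limited oscillation powers (uV^2), interhemispheric
#' asymmetry (amplitude gain (1+a)/(1-a) on right-hemisphere channels, so
#' realized left-right spectral asymmetry grows monotonically from 0 to 1),
#' the Hurst exponent of the common band-envelope modulation (long-range
#' temporal correlations), and a slow-modulation depth targeting the
#' MAD/median variability of 10-s alpha power.
#'
#' @param n_channels number of channels (first `n` of the 10-20 labels).
#' @param fs sampling rate in Hz.
#' @param duration recording duration in seconds (>= 60).
#' @param aperiodic_exponent,aperiodic_offset 1/f background parameters.
#' @param band_powers named band power targets in uV^2 (total in-band power,
#'   background included).
#' @param asymmetry fraction in `[0, 1]`.
#' @param envelope_hurst Hurst exponent of the band-envelope fGn, in (0, 1).
#' @param variability target MAD/median of 10-s alpha-band power.
#' @param seed integer master seed.
#' @return List of class `qeeg_profile`.
#' @export
eeg_profile <- function(n_channels = 19, fs = 256, duration = 600,
                        aperiodic_exponent = 1.5, aperiodic_offset = 1,
                        band_powers = c(delta = 40, theta = 15,
                                        alpha = 20, beta = 15),
                        asymmetry = 0.05, envelope_hurst = 0.7,
                        variability = 0.2, seed = 1) {
  stopifnot(asymmetry >= 0, asymmetry <= 1,
            all(band_powers >= 0), aperiodic_exponent >= 0,
            envelope_hurst > 0, envelope_hurst < 1)
  bands <- band_scheme()
  if (fs <= 2 * max(unlist(bands))) stop("fs must exceed twice the highest band edge")
  structure(list(n_channels = n_channels, fs = fs, duration = duration,
                 aperiodic_exponent = aperiodic_exponent,
                 aperiodic_offset = aperiodic_offset,
                 band_powers = band_powers, asymmetry = asymmetry,
                 envelope_hurst = envelope_hurst, variability = variability,
                 seed = seed),
            class = "qeeg_profile")
}

right_labels <- function() homologous_pairs()[, "right"]
left_labels <- function() homologous_pairs()[, "left"]

#' Generate a synthetic multichannel EEG recording
#'
#' Each channel is the sum of (i) a 1/f^alpha background synthesized by
#' spectral shaping of white noise with random phases and (ii) one
#' narrow-band Gaussian oscillation per frequency band, amplitude-modulated
#' by a band-specific envelope shared across channels. The envelope is an
#' affine transform of smoothed fractional Gaussian noise with the requested
#' Hurst exponent, plus a slow (< 0.05 Hz) modulation realizing the
#' variability target for the alpha band. Oscillation variances are scaled
#' so the realized total band powers match the profile targets; a symmetric
#' amplitude tilt (right hemisphere times `1 + asymmetry`, left times
#' `1 - asymmetry`) then realizes the target interhemispheric asymmetry.
#'
#' @param profile an [eeg_profile()].
#' @param channel_seeds optional integer vector of per-channel seeds
#'   (default distinct seeds derived from `profile$seed`); identical seeds
#'   yield identical channels, e.g. to construct perfectly symmetric
#'   left/right fixtures.
#' @param t_start_h hours after trauma of the first sample.
#' @return A [recording()].
#' @export
generate_recording <- function(profile, channel_seeds = NULL, t_start_h = 0) {
  stopifnot(inherits(profile, "qeeg_profile"))
  if (profile$duration < 60)
    stop("duration must be at least 60 s for envelope Hurst estimation")
  fs <- profile$fs
  n <- round(profile$duration * fs)
  nc <- profile$n_channels
  labels <- ten_twenty_labels()[seq_len(nc)]
  if (is.null(channel_seeds))  # reduced first so large seeds cannot overflow
    channel_seeds <- (as.numeric(profile$seed) %% 2e6) * 1000 + seq_len(nc)
  bands <- band_scheme()
  bnames <- names(bands)

  # Oscillations are synthesized at a decimated rate (the largest power of
  # two keeping every band safely below the decimated Nyquist),
  # amplitude-modulated there, summed, and band-limited-upsampled once; the
  # broadband 1/f background is synthesized at the full rate. Both use
  # direct spectral draws (complex Gaussian spectrum with the target
  # density, random phases).
  f_max <- max(vapply(bands, `[`, numeric(1), 2))
  dec <- max(1L, 2L^floor(log2(fs / (2.5 * f_max))))
  m <- n %/% dec
  fs_d <- fs / dec

  # shared band envelopes: lightly smoothed unit-SD fGn plus a slow
  # (sub-0.05 Hz) modulation realizing the variability target
  set.seed(profile$seed)
  env_seeds <- sample.int(2^30, length(bands))
  envs <- lapply(seq_along(bands), function(b) {
    g <- generate_fgn(profile$envelope_hurst, m, seed = env_seeds[b])
    g <- smooth_ma(g, max(1L, round(fs_d / 8)))
    g <- g / stats::sd(g)
    slow <- smooth_ma(stats::rnorm(m), round(10 * fs_d))
    slow <- slow / stats::sd(slow)
    cv <- if (bnames[b] == "alpha") profile$variability / 1.349 else
      profile$variability / 2.698
    pmax(0.05, 1 + 0.35 * g + cv * slow)
  })
  names(envs) <- bnames

  osc_var <- oscillation_variances(profile, bands)

  # per-channel standard normals, seeded per channel (identical seeds give
  # identical channels): one full-rate block for the background, one
  # decimated-rate block per band carrier
  Wbg <- matrix(0, n, nc)
  Wc <- lapply(bands, function(b) matrix(0, m, nc))
  for (ch in seq_len(nc)) {
    set.seed(channel_seeds[ch])
    Wbg[, ch] <- stats::rnorm(n)
    for (k in seq_along(bands)) Wc[[k]][, ch] <- stats::rnorm(m)
  }
  X <- spectral_noise(Wbg, fs, function(f)
    ifelse(f >= 0.45, 10^profile$aperiodic_offset /
             pmax(f, 0.45)^profile$aperiodic_exponent, 0))
  osc_sum <- matrix(0, m, nc)
  for (b in seq_along(bnames)) {
    if (osc_var[bnames[b]] <= 0) next
    carrier <- spectral_noise(Wc[[b]], fs_d, function(f)
      as.numeric(f >= bands[[b]][1] & f <= bands[[b]][2]))
    osc <- carrier * envs[[bnames[b]]]  # envelope recycles down columns
    s <- apply(osc, 2, stats::sd)
    s[s == 0] <- 1
    osc_sum <- osc_sum + osc * rep(sqrt(osc_var[bnames[b]]) / s, each = m)
  }
  X <- t(X + upsample_fft(osc_sum, dec))
  rownames(X) <- labels
  # symmetric amplitude tilt: right x (1 + a), left x (1 - a). The
  # homologous power ratio is then ((1+a)/(1-a))^2, giving a pairwise
  # symmetry index of exactly 2a/(1+a^2), while total power stays bounded
  # for any a in [0, 1).
  a <- profile$asymmetry
  X[labels %in% right_labels(), ] <- (1 + a) * X[labels %in% right_labels(), ]
  X[labels %in% left_labels(), ] <- (1 - a) * X[labels %in% left_labels(), ]
  recording(X, labels, fs, t_start_h)
}

# Oscillation variances solving the band-power targets given the analytic
# background power and the overlap of the printed band scheme (the beta
# band contains the upper alpha range, so targets couple linearly).
# Negative solutions are clipped to zero: those targets sit below what the
# background plus overlapping oscillations already supply.
oscillation_variances <- function(profile, bands = band_scheme()) {
  bnames <- names(bands)
  bg <- vapply(bands, function(b)
    aperiodic_band_power(profile$aperiodic_offset,
                         profile$aperiodic_exponent, b), numeric(1))
  tgt <- unlist(profile$band_powers)[bnames] - bg
  M <- outer(seq_along(bands), seq_along(bands), Vectorize(function(i, j) {
    ov <- min(bands[[i]][2], bands[[j]][2]) - max(bands[[i]][1], bands[[j]][1])
    max(ov, 0) / diff(bands[[j]])
  }))
  v <- tryCatch(solve(M, pmax(tgt, 0)), error = function(e) pmax(tgt, 0))
  stats::setNames(pmax(v, 0), bnames)
}

# Gaussian noise with a target one-sided PSD by direct spectral draw:
# consumes one samples x channels matrix of standard normals (as Re/Im
# pairs of the half-spectrum) so that per-channel seeding is reproducible,
# and needs a single inverse FFT per channel batch.
spectral_noise <- function(w, fs, psd_fun) {
  n <- nrow(w)
  nf <- n %/% 2
  S <- psd_fun(seq_len(nf - 1) * fs / n)
  amp <- sqrt(n * fs * S / 2)
  E <- (w[seq_len(nf - 1), , drop = FALSE] +
          1i * w[nf + seq_len(nf - 1), , drop = FALSE]) / sqrt(2)
  X <- matrix(0 + 0i, n, ncol(w))
  X[1 + seq_len(nf - 1), ] <- amp * E
  X[n + 1 - seq_len(nf - 1), ] <- Conj(amp * E)
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

# band-limited 'dec'-fold upsampling by zero-padding the spectrum
upsample_fft <- function(X, dec) {
  m <- nrow(X)
  n <- m * dec
  F <- stats::mvfft(X)
  half <- m %/% 2
  G <- matrix(0 + 0i, n, ncol(X))
  G[seq_len(half), ] <- F[seq_len(half), ]
  G[n + 1 - seq_len(half - 1), ] <- F[m + 1 - seq_len(half - 1), ]
  Re(stats::mvfft(G, inverse = TRUE)) / m
}

smooth_ma <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x, x[seq_len(k)]))  # circular pad
  y <- (cs[(k + 1):(k + n)] - cs[1:n]) / k
  # recentre the window (half-shift); circular so a rotation suffices
  shift <- k %/% 2
  c(y[(shift + 1):n], y[seq_len(shift)])
}

# integral of the 1/f^alpha one-sided PSD over a band (uV^2)
aperiodic_band_power <- function(offset, exponent, band) {
  A <- 10^offset
  if (abs(exponent - 1) < 1e-9) return(A * log(band[2] / band[1]))
  A * (band[2]^(1 - exponent) - band[1]^(1 - exponent)) / (1 - exponent)
}

#' Inject canonical artifacts into a recording
#'
#' Produces fixtures that violate exactly the artifact thresholds used in
#' preprocessing: `spike` writes a +300 uV pulse into one 10-s window,
#' `noise_burst` replaces a window with noise of variance well above
#' 1400 uV^2, and `flat_channel` zeroes a channel.
#'
#' @param rec a [recording()].
#' @param kind one of "spike", "flat_channel", "noise_burst".
#' @param channel channel index or label.
#' @param window 10-s window index (ignored for flat_channel).
#' @param amplitude spike amplitude in uV.
#' @param window_s window length in seconds.
#' @return The modified recording.
#' @export
inject_artifacts <- function(rec, kind = c("spike", "flat_channel", "noise_burst"),
                             channel = 1, window = 1, amplitude = 300,
                             window_s = 10) {
  stopifnot(inherits(rec, "qeeg_recording"))
  kind <- match.arg(kind)
  if (is.character(channel)) channel <- match(channel, rec$labels)
  wlen <- round(window_s * rec$fs)
  idx <- ((window - 1) * wlen + 1):(window * wlen)
  if (kind == "spike") {
    mid <- idx[wlen %/% 2]
    rec$samples[channel, mid + 0:3] <- amplitude
  } else if (kind == "flat_channel") {
    rec$samples[channel, ] <- 0
  } else {
    rec$samples[channel, idx] <- stats::rnorm(wlen, sd = 60)
  }
  rec
}

#' Synthetic cohort specification
#'
#' Defines a synthetic TBI cohort: number of patients, prevalence of poor
#' outcome, standardized effect sizes separating the outcome classes on the
#' generative knobs, monitoring timepoints, and the clinical covariate
#' model. Positive effect sizes act in the direction associated with poor
#' outcome: lower alpha power and alpha variability, higher delta power,
#' higher asymmetry (BSI), higher age.
#'
#' @param n_patients cohort size (>= 2 per class expected).
#' @param p_poor fraction with poor outcome, in (0, 1).
#' @param effect_sizes named standardized shifts between classes; recognised
#'   names: alpha_power, delta_power, asymmetry, variability, envelope_hurst.
#' @param timepoints monitoring timepoints in hours after trauma.
#' @param covariate_model named list per covariate: `mean`, `sd`, `shift`
#'   (standardized class shift, continuous) or `p_good`, `p_poor`
#'   (binary/count probabilities).
#' @param seed integer master seed.
#' @return List of class `qeeg_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 60, p_poor = 0.5,
                        effect_sizes = c(alpha_power = 1, delta_power = 1,
                                         asymmetry = 1, variability = 1,
                                         envelope_hurst = 0),
                        timepoints = c(12, 24, 48, 72, 96),
                        covariate_model = default_covariate_model(),
                        seed = 1) {
  stopifnot(p_poor > 0, p_poor < 1, n_patients >= 4)
  structure(list(n_patients = n_patients, p_poor = p_poor,
                 effect_sizes = effect_sizes, timepoints = timepoints,
                 covariate_model = covariate_model, seed = seed),
            class = "qeeg_cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_covariate_model <- function() {
  list(
    age        = list(mean = 50, sd = 15, shift = 0.9),
    motor      = list(type = "ordinal", levels = 1:6, shift = -0.5),
    pupils     = list(type = "ordinal", levels = 0:2, shift = 0.4),
    hypoxia    = list(type = "binary", p_good = 0.15, p_poor = 0.3),
    hypotension = list(type = "binary", p_good = 0.15, p_poor = 0.3),
    ct_class   = list(type = "ordinal", levels = 1:6, shift = 0.5),
    tsah       = list(type = "binary", p_good = 0.35, p_poor = 0.5),
    epidural   = list(type = "binary", p_good = 0.12, p_poor = 0.12),
    glucose    = list(mean = 8, sd = 2, shift = 0.4),
    hemoglobin = list(mean = 8.5, sd = 1, shift = -0.4)
  )
}

#' Generate a synthetic cohort
#'
#' Draws outcome labels with prevalence `p_poor`, per-patient clinical
#' covariates from the class-conditional covariate model, and a per-patient,
#' per-timepoint EEG generation profile whose knobs are shifted between the
#' classes by the standardized `effect_sizes`. Recordings are realized
#' lazily through [cohort_recording()] so that arbitrarily large cohorts
#' stay within memory. Fully deterministic under the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param duration recording duration in seconds per timepoint (default
#'   1800 = the 30 minutes around each timepoint).
#' @param fs sampling rate in Hz of the generated recordings.
#' @return List of class `qeeg_cohort` with `table` (one row per patient:
#'   patient_id, outcome, covariates) and `profiles`
#'   (`profiles[[patient]][[timepoint]]`), plus the spec.
#' @export
generate_cohort <- function(spec, duration = 1800, fs = 256) {
  stopifnot(inherits(spec, "qeeg_cohort_spec"))
  set.seed(spec$seed)
  np <- spec$n_patients
  outcome <- stats::rbinom(np, 1, spec$p_poor)
  # guarantee both classes at the stated minimum
  while (sum(outcome) < 2 || sum(1 - outcome) < 2)
    outcome <- stats::rbinom(np, 1, spec$p_poor)
  covs <- draw_covariates(spec$covariate_model, outcome)
  tab <- data.frame(patient_id = sprintf("P%03d", seq_len(np)),
                    outcome = outcome, covs,
                    stringsAsFactors = FALSE)
  es <- spec$effect_sizes
  getes <- function(nm) if (nm %in% names(es)) es[[nm]] else 0
  # between-patient SDs of the generative knobs (log scale for powers)
  base <- eeg_profile()
  profiles <- vector("list", np)
  for (p in seq_len(np)) {
    d <- outcome[p]  # 1 = poor
    profiles[[p]] <- stats::setNames(lapply(spec$timepoints, function(tp) {
      alpha_lp <- stats::rnorm(1, log(20) - d * getes("alpha_power") * 0.4, 0.4)
      delta_lp <- stats::rnorm(1, log(40) + d * getes("delta_power") * 0.4, 0.4)
      theta_lp <- stats::rnorm(1, log(15), 0.4)
      beta_lp  <- stats::rnorm(1, log(15), 0.4)
      asym <- stats::plogis(stats::rnorm(1, -2.5 + d * getes("asymmetry") * 0.8, 0.8))
      vari <- exp(stats::rnorm(1, log(0.25) - d * getes("variability") * 0.5, 0.5))
      hur <- min(0.95, max(0.55,
        stats::rnorm(1, 0.7 + d * getes("envelope_hurst") * 0.08, 0.08)))
      eeg_profile(n_channels = base$n_channels, fs = fs,
                  duration = duration,
                  aperiodic_exponent = max(0.5, stats::rnorm(1, 1.5, 0.2)),
                  aperiodic_offset = stats::rnorm(1, 1, 0.15),
                  band_powers = c(delta = exp(delta_lp), theta = exp(theta_lp),
                                  alpha = exp(alpha_lp), beta = exp(beta_lp)),
                  asymmetry = asym, envelope_hurst = hur, variability = vari,
                  seed = (as.numeric(spec$seed) %% 2e5) * 10000 +
                    p * 100 + which(spec$timepoints == tp))
    }), paste0("t", spec$timepoints))
  }
  structure(list(table = tab, profiles = profiles, spec = spec,
                 duration = duration),
            class = "qeeg_cohort")
}

draw_covariates <- function(model, outcome) {
  np <- length(outcome)
  out <- lapply(names(model), function(nm) {
    m <- model[[nm]]
    if (!is.null(m$type) && m$type == "binary") {
      p <- ifelse(outcome == 1, m$p_poor, m$p_good)
      stats::rbinom(np, 1, p)
    } else if (!is.null(m$type) && m$type == "ordinal") {
      z <- stats::rnorm(np) + outcome * m$shift
      lv <- m$levels
      lv[pmin(length(lv), pmax(1, round((z + 2) / 4 * (length(lv) - 1)) + 1))]
    } else {
      m$mean + m$sd * (stats::rnorm(np) + outcome * m$shift)
    }
  })
  names(out) <- names(model)
  as.data.frame(out)
}

#' Realize one recording of a synthetic cohort
#'
#' @param cohort a `qeeg_cohort` from [generate_cohort()].
#' @param patient patient index or `patient_id`.
#' @param timepoint timepoint in hours (must be in the cohort spec).
#' @return A [recording()] starting 15 minutes before the timepoint.
#' @export
cohort_recording <- function(cohort, patient, timepoint) {
  stopifnot(inherits(cohort, "qeeg_cohort"))
  if (is.character(patient)) patient <- match(patient, cohort$table$patient_id)
  prof <- cohort$profiles[[patient]][[paste0("t", timepoint)]]
  if (is.null(prof)) stop("timepoint not in cohort spec")
  generate_recording(prof, t_start_h = timepoint - prof$duration / 7200)
}
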