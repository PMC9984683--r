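test_that("profile validation catches bad knobs", {
  expect_error(eeg_profile(fs = 30), "fs")
  expect_error(eeg_profile(envelope_hurst = 1.2))
  expect_s3_class(eeg_profile(), "qeeg_profile")
})

test_that("generation is deterministic under the profile seed", {
  prof <- eeg_profile(duration = 60, fs = 128, seed = 9)
  r1 <- generate_recording(prof)
  r2 <- generate_recording(prof)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_recording(eeg_profile(duration = 60, fs = 128, seed = 10))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("identical channel seeds give identical channels", {
  prof <- eeg_profile(n_channels = 4, duration = 60, fs = 128,
                      asymmetry = 0, seed = 3)
  rec <- generate_recording(prof, channel_seeds = c(7, 7, 8, 9))
  expect_identical(rec$samples[1, ], rec$samples[2, ])
  expect_false(identical(rec$samples[3, ], rec$samples[4, ]))
})

test_that("realized band powers track the profile targets", {
  prof <- eeg_profile(duration = 600, fs = 128, seed = 21, asymmetry = 0)
  rec <- generate_recording(prof)
  spec <- welch_psd(rec$samples, fs = rec$fs)
  bp <- band_powers(spec)
  target <- prof$band_powers
  for (b in names(target))
    expect_equal(unname(bp$abs_power[b]), unname(target[b]),
                 tolerance = 0.15, label = paste("band", b))
})

test_that("the asymmetry knob maps onto the pairwise symmetry index", {
  bsis <- vapply(c(0, 0.1, 0.3), function(a) {
    rec <- generate_recording(eeg_profile(duration = 300, fs = 128,
                                          asymmetry = a, seed = 4))
    bsi(welch_psd(rec$samples, fs = rec$fs))
  }, numeric(1))
  expect_true(all(diff(bsis) > 0))
  # theory for a pure amplitude tilt: BSI = 2a/(1 + a^2); estimation noise
  # adds a small positive bias at a = 0
  expect_equal(bsis[2], 2 * 0.1 / (1 + 0.01), tolerance = 0.2)
  expect_equal(bsis[3], 2 * 0.3 / (1 + 0.09), tolerance = 0.1)
  # a = 0 is limited by the estimation-noise floor of |R - L|/(R + L)
  expect_lt(bsis[1], 0.15)
})

test_that("the aperiodic exponent knob shifts the fitted exponent", {
  ex <- vapply(c(1.0, 2.0), function(a) {
    rec <- generate_recording(eeg_profile(duration = 300, fs = 128,
                                          aperiodic_exponent = a,
                                          band_powers = c(delta = 0, theta = 0,
                                                          alpha = 0, beta = 0),
                                          seed = 5))
    fit_aperiodic(welch_psd(rec$samples, fs = rec$fs))$exponent
  }, numeric(1))
  # with no oscillations the fit recovers the knob closely
  expect_equal(ex[1], 1.0, tolerance = 0.1)
  expect_equal(ex[2], 2.0, tolerance = 0.1)
})

test_that("the envelope Hurst knob shifts delta-band amplitude LRTC", {
  h_of <- function(h) {
    rec <- generate_recording(eeg_profile(duration = 600, fs = 128,
                                          envelope_hurst = h, seed = 6))
    lrtc_amplitude(rec$samples, band = c(0.5, 4), fs = rec$fs)$hurst
  }
  expect_gt(h_of(0.85) - h_of(0.55), 0.1)
})

test_that("injected artifacts produce the intended violations", {
  rec <- generate_recording(eeg_profile(duration = 120, fs = 128, seed = 7))
  spiked <- inject_artifacts(rec, "spike", channel = 3, window = 2,
                             amplitude = 300)
  idx <- (128 * 10 + 1):(128 * 20)
  expect_gte(max(abs(spiked$samples[3, idx])), 200)
  flat <- inject_artifacts(rec, "flat_channel", channel = 5)
  expect_equal(stats::var(flat$samples[5, ]), 0)
  noisy <- inject_artifacts(rec, "noise_burst", channel = 2, window = 4)
  idx4 <- (128 * 30 + 1):(128 * 40)
  expect_gte(stats::var(noisy$samples[2, idx4]), 1400)
})

test_that("cohort generation is deterministic with labelled classes and covariates", {
  spec <- cohort_spec(n_patients = 8, timepoints = c(24, 48), seed = 11)
  c1 <- generate_cohort(spec, duration = 60, fs = 128)
  c2 <- generate_cohort(spec, duration = 60, fs = 128)
  expect_identical(c1$table, c2$table)
  expect_s3_class(c1, "qeeg_cohort")
  expect_equal(nrow(c1$table), 8)
  expect_gte(sum(c1$table$outcome == 1), 2)
  expect_gte(sum(c1$table$outcome == 0), 2)
  expect_true(all(names(default_covariate_model()) %in% names(c1$table)))
  expect_true(all(c1$table$motor %in% 1:6))
  expect_true(all(c1$table$hypoxia %in% 0:1))

  rec <- cohort_recording(c1, 1, 24)
  expect_s3_class(rec, "qeeg_recording")
  expect_equal(n_samples(rec), 60 * 128)
  # recording is centred on the timepoint
  expect_equal(rec$t_start_h + 60 / 7200, 24)
  expect_identical(rec$samples, cohort_recording(c1, c1$table$patient_id[1], 24)$samples)
})

test_that("planted effect sizes shift the class-conditional knobs", {
  spec <- cohort_spec(n_patients = 40,
                      effect_sizes = c(alpha_power = 2, asymmetry = 2,
                                       variability = 2),
                      timepoints = 24, seed = 12)
  coh <- generate_cohort(spec, duration = 60, fs = 128)
  alpha_knob <- vapply(seq_len(40), function(p)
    coh$profiles[[p]]$t24$band_powers[["alpha"]], numeric(1))
  asym_knob <- vapply(seq_len(40), function(p)
    coh$profiles[[p]]$t24$asymmetry, numeric(1))
  poor <- coh$table$outcome == 1
  expect_lt(mean(log(alpha_knob[poor])), mean(log(alpha_knob[!poor])))
  expect_gt(mean(asym_knob[poor]), mean(asym_knob[!poor]))
})

test_that("covariate model separates classes in the planted direction", {
  spec <- cohort_spec(n_patients = 200, timepoints = 24, seed = 13)
  coh <- generate_cohort(spec, duration = 60, fs = 128)
  poor <- coh$table$outcome == 1
  expect_gt(mean(coh$table$age[poor]), mean(coh$table$age[!poor]))
  expect_lt(mean(coh$table$motor[poor]), mean(coh$table$motor[!poor]))
})
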