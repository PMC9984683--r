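# Shared fixtures, computed lazily and cached for the whole test run.
# Everything here is deterministic (fixed seeds) so tests are reproducible.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A default-profile 30-minute recording (128 Hz, 19 channels).
fix_recording <- function() {
  fixture("recording_default", function() {
    generate_recording(eeg_profile(duration = 1800, fs = 128, seed = 101))
  })
}

# The same recording preprocessed: band-passed, common-average referenced,
# with artifact mask and the segment set around the 15-minute mark.
fix_preprocessed <- function() {
  fixture("preprocessed_default", function() {
    rec <- bandpass(fix_recording())
    rec <- common_average(rec)
    mask <- detect_artifacts(rec)
    segset <- extract_segments(rec, timepoint = 0.25, mask)
    list(rec = rec, mask = mask, segset = segset,
         seg = segset$segments[[1]])
  })
}

# A small 12-patient cohort feature table for predict/report unit tests
# (structure and invariants, not statistical power).
fix_small_table <- function() {
  fixture("small_table", function() {
    spec <- cohort_spec(n_patients = 12, p_poor = 0.5,
                        effect_sizes = c(alpha_power = 2, asymmetry = 2,
                                         variability = 2),
                        timepoints = 24, seed = 77)
    coh <- generate_cohort(spec, duration = 1800, fs = 128)
    extract_cohort_features(coh)
  })
}

# The 60-patient planted-effect cohort used by the end-to-end acceptance
# block: 2-SD shifts in alpha power, asymmetry (BSI) and band-power
# variability; one timepoint; three 10-minute segments per patient.
fix_cohort60 <- function() {
  fixture("cohort60", function() {
    spec <- cohort_spec(n_patients = 60, p_poor = 0.5,
                        effect_sizes = c(alpha_power = 2, asymmetry = 2,
                                         variability = 2),
                        timepoints = 24, seed = 42)
    coh <- generate_cohort(spec, duration = 1800, fs = 128)
    list(cohort = coh, features = extract_cohort_features(coh))
  })
}

# Clinical covariate column names used across predict tests.
covariate_names <- function() {
  c("age", "motor", "pupils", "hypoxia", "hypotension",
    "ct_class", "tsah", "epidural", "glucose", "hemoglobin")
}

# Patient-level label shuffle of a feature table (keeps the class balance,
# breaks any feature-outcome association).
shuffle_outcome <- function(tab) {
  ids <- unique(tab$patient_id)
  lab <- tab$outcome[match(ids, tab$patient_id)]
  map <- stats::setNames(sample(lab), ids)
  tab$outcome <- as.numeric(map[tab$patient_id])
  tab
}

# Path to the synthetic IMPACT coefficient config shipped with the package.
impact_config_path <- function() {
  system.file("extdata", "impact_coefficients_synthetic.yaml",
              package = "qeegtbi", mustWork = TRUE)
}
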