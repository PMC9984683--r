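# qeegtbi

Quantitative EEG outcome prediction for moderate-to-severe traumatic brain
injury (TBI).

Continuous EEG recorded at the ICU in the first days after severe head
trauma carries prognostic information: slowing of the spectrum, loss of
interhemispheric symmetry, reduced amplitude variability and altered
long-range temporal structure all associate with poor recovery. `qeegtbi`
implements a complete, tested analysis chain for this setting:

* **Synthetic cohort generation** — ICU-EEG recordings with controllable
  band powers, 1/f background, interhemispheric asymmetry, envelope Hurst
  exponent and band-power variability; cohorts with planted outcome
  effects and class-conditional clinical covariates; EDF export/import.
  Real patient recordings cannot be redistributed, so the generator stands
  in for them and makes every downstream stage testable.
* **Preprocessing** — zero-phase 0.1–40 Hz sixth-order Butterworth
  band-pass, common average reference, threshold-based artifact masking
  (±200 µV; window variance ≥ 1400 or ≤ 1 µV²; flat channels ≤ 0.1 µV²)
  in 10-s windows, and segmentation into three 10-minute segments around
  the 12/24/48/72/96-hour monitoring timepoints.
* **Feature extraction** — sixteen quantitative EEG feature families per
  segment (37 values): band powers, alpha/delta ratio, spectral edge,
  band-power variability, brain symmetry index, coherence, spectral
  entropy, amplitude regularity, aperiodic (1/f) offset and exponent, and
  per-band detrended fluctuation analysis of amplitude and phase dynamics
  plus broken-detailed-balance statistics (entropy production, flux curl).
* **Prediction** — 200-tree random forest with 5-fold patient-grouped
  stratified cross-validation and 3-segment augmentation, Youden operating
  point from training out-of-bag scores, backward feature elimination,
  McNemar model comparison with Benjamini–Hochberg correction, and an
  IMPACT-style logistic clinical baseline consumed as configuration.

## Quick start

Generate a 30-minute synthetic recording and run the full per-recording
pipeline:

```r
library(qeegtbi)

profile <- eeg_profile(duration = 1800, fs = 128,
                       band_powers = c(delta = 40, theta = 15,
                                       alpha = 20, beta = 15),
                       asymmetry = 0.1, seed = 1)
rec <- generate_recording(profile)
rec
#> <qeeg_recording> 19 channels x 230400 samples (1800.0 s @ 128 Hz), start 0.0 h after trauma

features <- process_recording(rec, timepoint = 0.25, patient_id = "P001")
round(features[1, c("abs_power.delta", "abs_power.alpha", "adr", "bsi",
                    "sef90", "aperiodic_exponent", "dfa_amp.delta")], 3)
#>   abs_power.delta abs_power.alpha    adr   bsi  sef90 aperiodic_exponent
#> 1          39.238          17.051 -0.394 0.188 11.995              2.366
#>   dfa_amp.delta
#> 1         0.783
```

Cohort-level outcome prediction (a 60-patient cohort with planted 2-SD
effects in alpha power, asymmetry and variability; extraction takes a few
minutes):

```r
spec <- cohort_spec(n_patients = 60,
                    effect_sizes = c(alpha_power = 2, asymmetry = 2,
                                     variability = 2),
                    timepoints = 24, seed = 42)
cohort <- generate_cohort(spec, fs = 128)
ft <- extract_cohort_features(cohort)

cv <- crossvalidate(ft, timepoints = 24, seed = 1)
cv
#> <qeeg_cv> timepoint(s) 24 h: mean AUC 0.914 (folds: 1.00 0.89 0.91 0.91 0.86)

head(importance_report(cv), 5)
#>             feature source importance
#> 1               bsi    EEG   9.947559
#> 2 variability.alpha    EEG   6.809127
#> 3   abs_power.alpha    EEG   6.533105
#> 4  variability.beta    EEG   4.767585
#> 5     dfa_amp.alpha    EEG   4.172726
```

Combine EEG with the clinical covariates, or score an IMPACT-style
logistic baseline from a coefficient config:

```r
comb <- combined_model(ft, timepoints = 24)
p <- impact_score(cohort$table,
                  system.file("extdata", "impact_coefficients_synthetic.yaml",
                              package = "qeegtbi"))
```

See the methods vignette (`vignettes/methods.Rmd`) for the generator
model, all feature definitions, the cross-validation protocol and the
numerical choices.

## Tests

```r
testthat::test_dir("tests/testthat", package = "qeegtbi",
                   load_package = "installed")
```

The suite includes per-module unit and property tests plus an acceptance
file (`tests/testthat/test-acceptance.R`) with analytic anchors (DFA of
white noise, BSI/coherence/regularity endpoints, closed-form entropy
production, exact aperiodic recovery, artifact precision/recall) and an
end-to-end anti-leakage check on a 60-patient synthetic cohort. The full
suite takes roughly 15 minutes on one CPU; everything except the cohort
check finishes in about 4.

## Scope and caveats

* The generator reproduces the statistical structure the analysis assumes
  (spectra, asymmetry, envelope dynamics), not real neural dynamics;
  published clinical performance cannot be reproduced without patient
  data.
* Narrow-band envelopes are smooth below one oscillation cycle, so
  envelope DFA in the higher bands is upward-biased by construction; the
  delta band recovers planted Hurst exponents accurately (see vignette).
* Published IMPACT regression coefficients are not redistributed; supply
  them as configuration. The YAML shipped under `inst/extdata/` is
  synthetic and for testing only.
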