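#' Standard 10-20 scalp montage and frequency bands
#'
#' Channel bookkeeping for the 19-electrode 10-20 International System
#' montage used in ICU EEG monitoring, plus the classical frequency band
#' scheme (delta 0.5-4, theta 4-8, alpha 8-13, beta 10-20 Hz; the alpha and
#' beta bands overlap by construction).
#'
#' @format `ten_twenty_labels()` returns a character vector of 19 labels.
#' @name montage
NULL

#' @rdname montage
#' @export
ten_twenty_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' @rdname montage
#' @return `homologous_pairs()`: two-column character matrix (left, right).
#' @export
homologous_pairs <- function() {
  cbind(left  = c("Fp1", "F3", "F7", "C3", "T3", "P3", "T5", "O1"),
        right = c("Fp2", "F4", "F8", "C4", "T4", "P4", "T6", "O2"))
}

#' @rdname montage
#' @return `band_scheme()`: named list of c(low, high) band edges in Hz.
#' @export
band_scheme <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(10, 20))
}

#' @rdname montage
#' @export
band_names <- function() names(band_scheme())

# Frequency range over which broadband spectral features are evaluated;
# matches the 0.1-40 Hz acquisition band-pass with the sub-0.5 Hz rolloff
# excluded.
analysis_range <- function() c(0.5, 40)
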