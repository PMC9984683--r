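#' The sixteen quantitative EEG feature families
#'
#' Inventory of the feature families extracted from each clean 10-minute
#' segment. Seven families are band-resolved (one value per frequency band);
#' the remainder are broadband scalars.
#'
#' @return data.frame with columns `family` and `band_resolved`.
#' @export
feature_families <- function() {
  data.frame(
    family = c("total_power", "abs_power", "rel_power", "adr", "sef90",
               "variability", "bsi", "coherence", "shannon_entropy",
               "regularity", "aperiodic_offset", "aperiodic_exponent",
               "dfa_amp", "dfa_phase", "entropy_production", "flux_curl"),
    band_resolved = c(FALSE, TRUE, TRUE, FALSE, FALSE,
                      TRUE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, FALSE,
                      TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Expanded feature column names
#'
#' Band-resolved families are expanded to one column per band, named
#' `family.band` (e.g. `abs_power.delta`).
#'
#' @export
feature_names <- function() {
  ff <- feature_families()
  unlist(lapply(seq_len(nrow(ff)), function(i) {
    if (ff$band_resolved[i]) paste(ff$family[i], band_names(), sep = ".")
    else ff$family[i]
  }), use.names = FALSE)
}

#' Extract all feature families from one segment
#'
#' Computes the full quantitative EEG feature vector of a clean segment:
#' Welch spectral features (band powers, alpha/delta ratio, spectral edge,
#' band-power variability, brain symmetry index, spectral entropy),
#' coherence, amplitude regularity, the aperiodic 1/f fit, per-band
#' detrended fluctuation analysis of the summed amplitude envelope and of
#' the Kuramoto order parameter, and per-band broken-detailed-balance
#' measures (entropy production and flux curl of the 9-state transition
#' model). Welch-based features skip artifact-flagged windows per channel;
#' time-domain multichannel features use the windows that are clean in
#' every retained channel.
#'
#' @param seg one segment from [extract_segments()] (or a channels x time
#'   matrix with `fs`).
#' @param fs sampling rate for matrix input.
#' @return Named numeric vector over [feature_names()].
#' @export
segment_features <- function(seg, fs = NULL) {
  seg <- as_segment(seg, fs)
  bands <- band_scheme()
  out <- stats::setNames(rep(NA_real_, length(feature_names())),
                         feature_names())

  spec <- welch_psd(seg)
  bp <- band_powers(spec)
  out["total_power"] <- bp$total_power
  out[paste0("abs_power.", band_names())] <- bp$abs_power
  out[paste0("rel_power.", band_names())] <- bp$rel_power
  out["adr"] <- alpha_delta_ratio(bp$abs_power)
  out["sef90"] <- sef90(spec)
  vb <- variability_all(seg)
  out[paste0("variability.", band_names())] <- vb
  out["bsi"] <- bsi(spec)
  out["coherence"] <- mean_coherence(seg)
  out["shannon_entropy"] <- shannon_entropy(spec)
  out["regularity"] <- regularity(seg)
  ap <- fit_aperiodic(spec)
  out["aperiodic_offset"] <- ap$offset
  out["aperiodic_exponent"] <- ap$exponent

  # time-domain dynamics on the all-channel-clean sample set; the band-
  # limited analytic signals are decimated 4-fold (all bands lie below the
  # decimated Nyquist), which leaves envelope, phase and the DFA window
  # rule (expressed in seconds) unchanged
  cseg <- common_clean_segment(seg)
  # multichannel dynamics need at least one minute clean in every channel
  if (ncol(cseg$samples) < 60 * cseg$fs) return(out)
  # largest power-of-two decimation keeping the decimated Nyquist a safe
  # margin above the highest band edge
  f_max <- max(vapply(bands, `[`, numeric(1), 2))
  dec <- max(1L, 2L^floor(log2(cseg$fs / (2.5 * f_max))))
  fs_d <- cseg$fs / dec
  As <- band_analytic_multi(cseg$samples, bands, cseg$fs, dec = dec)
  for (b in band_names()) {
    band <- bands[[b]]
    A <- As[[b]]
    env_sum <- colSums(Mod(A))
    out[paste0("dfa_amp.", b)] <- lrtc_dfa(env_sum, band, fs_d)$hurst
    R <- kuramoto_order(Arg(A))
    out[paste0("dfa_phase.", b)] <- lrtc_dfa(R, band, fs_d)$hurst
    traj <- pc_project(Re(A))
    tm <- transition_model(traj)
    out[paste0("entropy_production.", b)] <- tm$entropy_production
    out[paste0("flux_curl.", b)] <- tm$flux_curl
  }
  out
}

# band-power variability for every band from a single Welch pass
variability_all <- function(seg, window = 10, min_windows = 5) {
  fs <- seg$fs
  bands <- band_scheme()
  wlen <- round(window * fs)
  nw <- ncol(seg$samples) %/% wlen
  w <- hamming_window(wlen)
  U <- sum(w^2)
  nf <- wlen %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / wlen
  df <- fs / wlen
  acc <- matrix(NA_real_, nrow(seg$samples), length(bands),
                dimnames = list(NULL, names(bands)))
  for (ch in seq_len(nrow(seg$samples))) {
    ok <- which(seg$clean[seq_len(nw), ch])
    if (length(ok) < min_windows) next
    X <- matrix(seg$samples[ch, seq_len(nw * wlen)], nrow = wlen)[, ok, drop = FALSE]
    X <- sweep(X, 2, colMeans(X)) * w
    P <- abs(stats::mvfft(X))^2 / (fs * U)
    P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]
    for (b in names(bands)) {
      bp <- colSums(P[band_bins(freqs, bands[[b]]), , drop = FALSE]) * df
      med <- stats::median(bp)
      if (med > 0) acc[ch, b] <- stats::mad(bp, constant = 1) / med
    }
  }
  colMeans(acc, na.rm = TRUE)
}

# keep only 10-s windows clean in every channel, concatenated
common_clean_segment <- function(seg) {
  nw <- nrow(seg$clean)
  wlen <- ncol(seg$samples) %/% nw
  ok <- rowSums(!seg$clean) == 0
  if (all(ok)) return(seg)
  idx <- unlist(lapply(which(ok), function(w) ((w - 1) * wlen + 1):(w * wlen)))
  list(samples = seg$samples[, idx, drop = FALSE],
       clean = matrix(TRUE, sum(ok), ncol(seg$clean)),
       labels = seg$labels, fs = seg$fs)
}

# principal-component projection of an already-filtered matrix
pc_project <- function(X) {
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / ncol(X)
  eg <- eigen(C, symmetric = TRUE)
  V <- eg$vectors[, 1:2, drop = FALSE]
  sgn <- ifelse(colSums(V) < 0, -1, 1)
  V <- sweep(V, 2, sgn, "*")
  Y <- crossprod(V, X)
  sds <- apply(Y, 1, stats::sd)
  sds[sds == 0] <- 1
  Y <- Y / sds
  attr(Y, "var_explained") <- eg$values[1:2] / sum(pmax(eg$values, 0))
  rownames(Y) <- c("PC1", "PC2")
  Y
}

#' Extract the feature table of a segment set
#'
#' @param segset a `qeeg_segment_set` from [extract_segments()].
#' @param patient_id,timepoint_h identifiers carried into the table.
#' @return data.frame, one row per segment, with id columns followed by the
#'   expanded feature columns; `NULL` when the segment set is unavailable
#'   (all channels flat).
#' @export
extract_features <- function(segset, patient_id = "P000",
                             timepoint_h = segset$timepoint_h) {
  stopifnot(inherits(segset, "qeeg_segment_set"))
  if (!segset$available) return(NULL)
  rows <- lapply(seq_along(segset$segments), function(s) {
    fv <- segment_features(segset$segments[[s]])
    cbind(data.frame(patient_id = patient_id, timepoint_h = timepoint_h,
                     segment_id = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}

#' Preprocess a recording and extract features at one timepoint
#'
#' Runs the full per-recording pipeline: zero-phase band-pass, common
#' average reference, artifact masking, segmentation into three 10-minute
#' segments around the timepoint, and feature extraction.
#'
#' @param rec a raw [recording()] covering the 30 minutes around
#'   `timepoint`.
#' @param timepoint hours after trauma.
#' @param patient_id identifier carried into the feature table.
#' @return Feature data.frame as from [extract_features()], or `NULL` when
#'   no non-flat channel remains.
#' @export
process_recording <- function(rec, timepoint, patient_id = "P000") {
  rec <- bandpass(rec)
  rec <- common_average(rec)
  mask <- detect_artifacts(rec)
  segset <- extract_segments(rec, timepoint, mask)
  extract_features(segset, patient_id = patient_id, timepoint_h = timepoint)
}

#' Extract the feature table of a whole synthetic cohort
#'
#' Realizes each patient's recording at each requested timepoint, runs
#' [process_recording()], and row-binds the per-segment feature rows with
#' the cohort's outcome labels and clinical covariates.
#'
#' @param cohort a `qeeg_cohort` from [generate_cohort()].
#' @param timepoints subset of the cohort's timepoints (default all).
#' @param verbose print progress.
#' @return data.frame: patient_id, timepoint_h, segment_id, features,
#'   outcome, covariates.
#' @export
extract_cohort_features <- function(cohort, timepoints = cohort$spec$timepoints,
                                    verbose = FALSE) {
  stopifnot(inherits(cohort, "qeeg_cohort"))
  rows <- list()
  for (p in seq_len(nrow(cohort$table))) {
    pid <- cohort$table$patient_id[p]
    for (tp in timepoints) {
      rec <- cohort_recording(cohort, p, tp)
      ft <- process_recording(rec, tp, patient_id = pid)
      if (!is.null(ft)) rows[[length(rows) + 1]] <- ft
      if (verbose) message(pid, " t=", tp, "h done")
    }
  }
  feats <- do.call(rbind, rows)
  merge(feats, cohort$table, by = "patient_id", sort = FALSE)
}
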