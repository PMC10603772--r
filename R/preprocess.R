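#' Normalize an MS2 spectrum
#'
#' Rescales a raw spectrum onto the dimensionless coordinates all features
#' are computed in: intensities are divided by the base-peak (most intense)
#' intensity, so relative intensities lie in (0, 1] with the base peak at
#' exactly 1; m/z values are divided by the precursor m/z, so fragments
#' below the precursor map into (0, 1) and the precursor itself to ~1.
#' Peaks above the precursor (isotopes, adducts) keep mz > 1 and are not
#' clipped. Peak order is preserved.
#'
#' @param spectrum an [ms2_spectrum()].
#' @return An `ms2_spectrum_norm` object: same structure, with `peaks`
#'   holding normalized coordinates and `normalized = TRUE`. The raw
#'   `precursor_mz` is retained (features such as the 2-Da fragment density
#'   need it to restore Dalton units).
#' @export
normalize_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  pk <- spectrum$peaks
  if (nrow(pk)) {
    base <- max(pk[, "intensity"])
    if (base <= 0) stop("spectrum '", spectrum$id, "' has no peak with intensity > 0")
    pk[, "intensity"] <- pk[, "intensity"] / base
    pk[, "mz"] <- pk[, "mz"] / spectrum$precursor_mz
  }
  out <- spectrum
  out$peaks <- pk
  class(out) <- c("ms2_spectrum_norm", "ms2_spectrum")
  out
}

#' Remove noise peaks from a normalized spectrum
#'
#' Drops every peak whose relative intensity is less than or equal to the
#' noise threshold (default 5% of the base peak; the boundary value itself
#' is dropped). The result may have an empty peak list; downstream feature
#' extraction treats such spectra as zero-count objects rather than errors.
#'
#' @param spec an `ms2_spectrum_norm` from [normalize_spectrum()].
#' @param threshold relative-intensity noise cutoff in `[0, 1)`.
#' @return The spectrum with noise peaks removed. Idempotent.
#' @export
denoise_spectrum <- function(spec, threshold = 0.05) {
  stopifnot(inherits(spec, "ms2_spectrum_norm"))
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must be a single value in [0, 1)")
  keep <- spec$peaks[, "intensity"] > threshold
  spec$peaks <- spec$peaks[keep, , drop = FALSE]
  spec
}

#' Preprocess spectra for feature extraction
#'
#' Convenience composition of [normalize_spectrum()] and
#' [denoise_spectrum()] over a list of spectra.
#'
#' @param spectra list of [ms2_spectrum()] objects.
#' @param noise_threshold relative-intensity noise cutoff (default 0.05).
#' @return List of preprocessed `ms2_spectrum_norm` objects.
#' @export
preprocess_spectra <- function(spectra, noise_threshold = 0.05) {
  lapply(spectra, function(s) denoise_spectrum(normalize_spectrum(s), noise_threshold))
}
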