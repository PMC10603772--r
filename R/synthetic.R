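#' Configuration for the synthetic spectrum generator
#'
#' Distributional knobs for [generate_dataset()]. The defaults emulate the
#' data regime the classifier is meant for: ~1400 centroided MS2 spectra of
#' small molecules (precursor 100–900 Da) acquired at graded HCD collision
#' energies of 10–100%, with 44% of spectra providing good diagnostic
#' information. Good spectra carry 3–12 intense (10–100% relative),
#' well-spread diagnostic fragments, a subordinate precursor peak and light
#' sub-5% noise; poor spectra violate at least one of the five quality
#' criteria (see [rule_label()]), the violated criterion being drawn at
#' random and recorded in the spectrum's `meta`.
#'
#' @param n_spectra number of spectra to generate.
#' @param frac_good fraction labeled good (class counts are exact:
#'   `floor(frac_good * n_spectra)` good spectra).
#' @param precursor_mz_range precursor m/z range in Da.
#' @param ce_levels collision-energy levels (% HCD) sampled uniformly.
#' @param n_diagnostic_range number of diagnostic fragments in a good
#'   spectrum (inclusive range).
#' @param diag_intensity_range relative-intensity range of diagnostic
#'   fragments (the base peak is always one of them, at 1.0).
#' @param noise_intensity_range relative-intensity range of noise peaks;
#'   kept below the 5% noise-filter cutoff.
#' @param seed RNG seed used by [generate_dataset()].
#' @param thresholds quality-criteria thresholds, see [quality_thresholds()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_spectra = 1399,
                             frac_good = 0.44,
                             precursor_mz_range = c(100, 900),
                             ce_levels = c(10, 20, 35, 50, 65, 80, 100),
                             n_diagnostic_range = c(3, 12),
                             diag_intensity_range = c(0.1, 1.0),
                             noise_intensity_range = c(0.002, 0.045),
                             seed = 1L,
                             thresholds = quality_thresholds()) {
  stopifnot(n_spectra >= 0, frac_good >= 0, frac_good <= 1,
            all(precursor_mz_range > 0), diff(precursor_mz_range) >= 0,
            all(ce_levels >= 0), all(noise_intensity_range > 0))
  structure(list(n_spectra = n_spectra, frac_good = frac_good,
                 precursor_mz_range = precursor_mz_range,
                 ce_levels = ce_levels,
                 n_diagnostic_range = n_diagnostic_range,
                 diag_intensity_range = diag_intensity_range,
                 noise_intensity_range = noise_intensity_range,
                 seed = as.integer(seed), thresholds = thresholds),
            class = "synthetic_config")
}

#' Quantified spectrum-quality criteria thresholds
#'
#' The five criteria a spectrum must satisfy to be labeled good are
#' qualitative expert-judgment rules; these thresholds are the package's
#' operational quantification of them (see [rule_label()]). They can be
#' tightened or loosened to match a different labeling policy.
#'
#' @param floor relative-intensity floor separating diagnostic fragments
#'   from noise (criteria i/ii and v; peaks at or below it are noise).
#' @param min_frags minimum number of non-precursor fragments above the
#'   floor (criterion i).
#' @param span_frac minimum fraction of the range from the lowest retained
#'   fragment up to the precursor that the fragments must span (criterion iii).
#' @param precursor_pctile percentile of the retained fragment intensities
#'   that the precursor peak must not exceed (criterion iv).
#' @param noise_frac_max maximum tolerated pre-filter fraction of sub-floor
#'   peaks (criterion v).
#' @param precursor_tol normalized m/z tolerance for recognizing the
#'   precursor peak (|mz_norm - 1| <= tol).
#' @return Named list of thresholds.
#' @export
quality_thresholds <- function(floor = 0.05, min_frags = 2, span_frac = 0.5,
                               precursor_pctile = 0.25, noise_frac_max = 0.8,
                               precursor_tol = 0.01) {
  list(floor = floor, min_frags = min_frags, span_frac = span_frac,
       precursor_pctile = precursor_pctile, noise_frac_max = noise_frac_max,
       precursor_tol = precursor_tol)
}

#' Generate one synthetic MS2 spectrum
#'
#' Draws from the ambient RNG stream (callers control reproducibility via
#' `set.seed()`; [generate_dataset()] does this from `config$seed`). Good
#' spectra satisfy all five quality criteria by construction; poor spectra
#' violate at least the randomly drawn criterion recorded in
#' `meta$violation` (`"i"` too few diagnostic fragments, `"iii"` fragments
#' clustered in a narrow m/z window, `"iv"` precursor-dominated spectrum,
#' `"v"` drowned in sub-5% noise). Peaks are emitted in raw Da / raw count
#' units so the full normalize–denoise–featurize pipeline is exercised.
#'
#' @param config a [synthetic_config()].
#' @param class `"good"` or `"poor"`.
#' @param id spectrum identifier.
#' @return A labeled [ms2_spectrum()].
#' @export
generate_spectrum <- function(config, class = c("good", "poor"), id = "syn") {
  class <- match.arg(class)
  premz <- stats::runif(1, config$precursor_mz_range[1], config$precursor_mz_range[2])
  ce <- sample(config$ce_levels, 1)
  nr <- config$noise_intensity_range
  dr <- config$diag_intensity_range
  ndr <- config$n_diagnostic_range

  diag_block <- function(n, lo = 0.08, hi = 0.95, clustered = FALSE) {
    if (clustered) {
      ctr <- stats::runif(1, 0.3, 0.7)
      pos <- stats::runif(n, ctr - 0.04, ctr + 0.04)
    } else if (n >= 2) {
      pos <- c(stats::runif(1, lo, lo + 0.12),
               stats::runif(1, hi - 0.10, hi),
               if (n > 2) stats::runif(n - 2, lo, hi))
    } else pos <- stats::runif(n, lo, hi)
    int <- stats::runif(n, dr[1], dr[2])
    if (n) int[sample.int(n, 1)] <- 1  # one diagnostic fragment is the base peak
    list(pos = pos, int = int)
  }
  noise_block <- function(n) list(pos = stats::runif(n, 0.05, 1.05),
                                  int = stats::runif(n, nr[1], nr[2]))

  violation <- NA_character_
  if (class == "good") {
    n_diag <- sample(seq(ndr[1], ndr[2]), 1)
    d <- diag_block(n_diag)
    pos <- d$pos; int <- d$int
    if (stats::runif(1) < 0.7) {  # subordinate precursor peak
      q25 <- stats::quantile(int, config$thresholds$precursor_pctile, names = FALSE)
      pos <- c(pos, 1); int <- c(int, q25 * stats::runif(1, 0.1, 0.8))
    }
    n_noise <- sample(0:min(15, 3 * n_diag), 1)
    nb <- noise_block(n_noise)
    pos <- c(pos, nb$pos); int <- c(int, nb$int)
  } else {
    violation <- sample(c("i", "iii", "iv", "v"), 1)
    if (violation == "i") {          # 0-1 diagnostic fragments
      n_diag <- sample(0:1, 1)
      pos <- c(stats::runif(n_diag, 0.1, 0.9), 1)  # dominant precursor as base peak
      int <- c(stats::runif(n_diag, 0.06, 0.4), 1)
      nb <- noise_block(sample(2:4, 1))
      pos <- c(pos, nb$pos); int <- c(int, nb$int)
    } else if (violation == "iii") { # fragments clustered, no spread
      d <- diag_block(sample(4:8, 1), clustered = TRUE)
      nb <- noise_block(sample(0:4, 1))
      pos <- c(d$pos, nb$pos); int <- c(d$int, nb$int)
    } else if (violation == "iv") {  # precursor dominates the fragments
      n_diag <- sample(2:5, 1)
      d <- diag_block(n_diag)
      frag_int <- stats::runif(n_diag, 0.06, 0.3)
      nb <- noise_block(sample(0:4, 1))
      pos <- c(d$pos, 1, nb$pos); int <- c(frag_int, 1, nb$int)
    } else {                         # "v": buried in sub-floor noise
      n_diag <- sample(2:4, 1)
      d <- diag_block(n_diag)
      n_noise <- sample(ceiling(4.5 * n_diag):(8 * n_diag), 1)
      nb <- noise_block(n_noise)
      pos <- c(d$pos, nb$pos); int <- c(d$int, nb$int)
    }
  }
  scale <- 10^stats::runif(1, 4, 7)  # raw ion counts
  ms2_spectrum(id, premz, ce, mz = pos * premz, intensity = int * scale,
               label = class,
               meta = list(class = class, violation = violation))
}

#' Generate a labeled synthetic dataset
#'
#' Produces exactly `config$n_spectra` spectra with
#' `floor(config$frac_good * n)` good ones, in shuffled order, reproducible
#' from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return List of labeled [ms2_spectrum()] objects.
#' @examples
#' spectra <- generate_dataset(synthetic_config(n_spectra = 20, seed = 42))
#' table(spectrum_labels(spectra))
#' @export
generate_dataset <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n <- config$n_spectra
  n_good <- floor(config$frac_good * n)
  classes <- sample(rep(c("good", "poor"), c(n_good, n - n_good)))
  out <- vector("list", n)
  for (i in seq_len(n))
    out[[i]] <- generate_spectrum(config, classes[i],
                                  id = sprintf("syn_%05d", i))
  out
}

#' Rule-based quality labeling of a spectrum
#'
#' Scores a raw spectrum against quantified versions of the five
#' diagnostic-quality criteria (after normalization and noise filtering):
#'
#' 1. **(i) fragment count** — at least `min_frags` non-precursor peaks
#'    survive the intensity floor;
#' 2. **(ii) fragment intensity** — those fragments exceed the floor
#'    (the same 5% cutoff quantifies both criteria, so (ii) holds exactly
#'    when (i) does);
#' 3. **(iii) fragment spread** — the retained fragments span at least
#'    `span_frac` of the m/z range from the lowest fragment up to the
#'    precursor;
#' 4. **(iv) precursor dominance** — a retained precursor peak must not
#'    exceed the `precursor_pctile` quantile of the fragment intensities
#'    (vacuously true if no precursor peak survives);
#' 5. **(v) noise level** — at most `noise_frac_max` of the pre-filter
#'    peaks are sub-floor noise.
#'
#' The label is good iff all five pass.
#'
#' @param spectrum an [ms2_spectrum()] (raw units).
#' @param thresholds see [quality_thresholds()].
#' @return List with `label` (`"good"`/`"poor"`) and `criteria`, a named
#'   logical vector `c(i, ii, iii, iv, v)`.
#' @export
rule_label <- function(spectrum, thresholds = quality_thresholds()) {
  th <- thresholds
  norm <- normalize_spectrum(spectrum)
  pre_n <- nrow(norm$peaks)
  noise_frac <- if (pre_n) sum(norm$peaks[, "intensity"] <= th$floor) / pre_n else 0
  spec <- denoise_spectrum(norm, th$floor)
  pk <- spec$peaks
  is_prec <- abs(pk[, "mz"] - 1) <= th$precursor_tol
  frag <- pk[!is_prec, , drop = FALSE]

  crit_i <- nrow(frag) >= th$min_frags
  crit_ii <- crit_i  # the intensity floor quantifies both (i) and (ii)
  crit_iii <- if (nrow(frag) >= 2) {
    span <- max(frag[, "mz"]) - min(frag[, "mz"])
    span >= th$span_frac * (1 - min(frag[, "mz"]))
  } else FALSE
  crit_iv <- if (!any(is_prec)) TRUE
  else if (!nrow(frag)) FALSE
  else max(pk[is_prec, "intensity"]) <=
    stats::quantile(frag[, "intensity"], th$precursor_pctile, names = FALSE)
  crit_v <- noise_frac <= th$noise_frac_max

  criteria <- c(i = crit_i, ii = crit_ii, iii = crit_iii, iv = crit_iv, v = crit_v)
  list(label = if (all(criteria)) "good" else "poor", criteria = criteria)
}
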