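#' Spectrum centroid in normalized (m/z, intensity) space
#'
#' The centroid is a single representative point of the peak cloud: its m/z
#' coordinate is the intensity-weighted mean of the normalized m/z values,
#' \eqn{m_c = \sum m_j i_j / \sum i_j}, and its intensity coordinate is the
#' arithmetic mean intensity, \eqn{i_c = \sum i_j / n}. Per-peak Euclidean
#' distances to this point are the raw material of the distance feature
#' family.
#'
#' @param spec a preprocessed `ms2_spectrum_norm` with at least one peak.
#' @return Named numeric vector `c(mz, intensity)`.
#' @export
compute_centroid <- function(spec) {
  stopifnot(inherits(spec, "ms2_spectrum_norm"))
  pk <- spec$peaks
  if (!nrow(pk)) stop("centroid undefined for an empty spectrum ('", spec$id, "')")
  c(mz = sum(pk[, "mz"] * pk[, "intensity"]) / sum(pk[, "intensity"]),
    intensity = mean(pk[, "intensity"]))
}

peak_centroid_distances <- function(spec) {
  pk <- spec$peaks
  if (!nrow(pk)) return(numeric(0))
  ctr <- compute_centroid(spec)
  sqrt((pk[, "mz"] - ctr[["mz"]])^2 + (pk[, "intensity"] - ctr[["intensity"]])^2)
}

globals_of <- function(spec)
  c(precursor_mz = spec$precursor_mz, collision_energy = spec$collision_energy)

#' Distance feature family
#'
#' Summary statistics of the per-peak Euclidean distances to the spectrum
#' centroid (see [compute_centroid()]): count, mean, standard deviation,
#' minimum, maximum and the three quartiles, followed by the two global
#' descriptors (precursor m/z, collision energy) — 10 values. An empty
#' spectrum yields zero statistics with count 0; a single peak is its own
#' centroid, so all distance statistics are 0 with count 1.
#'
#' @param spec a preprocessed `ms2_spectrum_norm`.
#' @return Named numeric vector of length 10 with `attr(, "family") = "distance"`.
#' @export
distance_features <- function(spec) {
  d <- peak_centroid_distances(spec)
  stats <- if (length(d)) {
    q <- unname(stats::quantile(d, c(0.25, 0.5, 0.75)))
    c(length(d), mean(d), if (length(d) > 1) stats::sd(d) else 0,
      min(d), max(d), q)
  } else rep(0, 8)
  out <- c(stats::setNames(stats, c("d_count", "d_mean", "d_sd", "d_min",
                                    "d_max", "d_q1", "d_q2", "d_q3")),
           globals_of(spec))
  attr(out, "family") <- "distance"
  out
}

#' Shannon entropy of a nonnegative vector
#'
#' Values are normalized to a probability vector \eqn{p_k = v_k / \sum v},
#' and \eqn{-\sum p_k \ln p_k} is returned, with the convention
#' \eqn{0 \ln 0 = 0}. Empty or all-zero input gives 0. Natural log, so a
#' uniform n-vector attains the maximum \eqn{\ln n}.
#'
#' @param values numeric vector, all entries >= 0.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(values) {
  if (any(values < 0)) stop("shannon_entropy requires nonnegative values")
  tot <- sum(values)
  if (!length(values) || tot == 0) return(0)
  p <- values[values > 0] / tot
  -sum(p * log(p))
}

#' Intensity balance along the m/z axis
#'
#' The m/z axis (normalized units, spanning `[0, max(mz)]`) is divided into
#' `n_bins` equal-width bins; the result is the summed intensity of bins
#' 2..n minus the summed intensity of the first bin. Positive values mean
#' the intensity mass sits above the lowest-m/z slice. Bins are left-closed
#' (`[a, b)`), the last bin right-closed. An empty spectrum returns 0.
#'
#' @param spec a preprocessed `ms2_spectrum_norm`.
#' @param n_bins number of equal-width m/z bins (>= 2, default 10).
#' @return Signed intensity difference.
#' @export
intensity_balance <- function(spec, n_bins = 10) {
  stopifnot(n_bins >= 2)
  pk <- spec$peaks
  if (!nrow(pk)) return(0)
  w <- max(pk[, "mz"]) / n_bins
  idx <- pmin(n_bins, floor(pk[, "mz"] / w) + 1L)
  first <- sum(pk[idx == 1L, "intensity"])
  sum(pk[, "intensity"]) - 2 * first
}

#' Handcrafted feature family
#'
#' Twelve peak-list descriptors drawn from the spectrum-quality literature,
#' in fixed order, followed by precursor m/z and collision energy — 14
#' values:
#'
#' * `n_peaks` — number of retained peaks;
#' * `int_mean`, `int_sum`, `int_sd` — moments of the relative intensities;
#' * `dot_mz_int` — dot product of normalized m/z and intensity vectors,
#'   a measure of m/z–intensity alignment;
#' * `n_gt_0.1`, `n_gt_0.2` — peaks with relative intensity > 0.1 / > 0.2;
#' * `mz_diff_sd` — standard deviation of consecutive normalized m/z gaps
#'   (0 with fewer than 2 peaks);
#' * `frags_per_2da` — mean number of fragments per 2-Dalton window,
#'   computed on de-normalized (raw Da) m/z, windows tiling
#'   `[min m/z, max m/z]`;
#' * `intensity_balance` — see [intensity_balance()];
#' * `entropy_mz`, `entropy_int` — Shannon entropies of the m/z and
#'   intensity vectors ([shannon_entropy()]).
#'
#' Empty spectra yield all-zero descriptors (the globals are still
#' appended), so heavily filtered input never crashes prediction.
#'
#' @param spec a preprocessed `ms2_spectrum_norm`.
#' @param balance_bins bins for the intensity balance (default 10).
#' @return Named numeric vector of length 14 with
#'   `attr(, "family") = "handcrafted"`.
#' @export
handcrafted_features <- function(spec, balance_bins = 10) {
  pk <- spec$peaks
  n <- nrow(pk)
  if (n) {
    mz <- pk[, "mz"]; int <- pk[, "intensity"]
    raw_mz <- mz * spec$precursor_mz
    n_win <- max(1, ceiling((max(raw_mz) - min(raw_mz)) / 2))
    vals <- c(
      n_peaks = n,
      int_mean = mean(int),
      int_sum = sum(int),
      int_sd = if (n > 1) stats::sd(int) else 0,
      dot_mz_int = sum(mz * int),
      n_gt_0.1 = sum(int > 0.1),
      n_gt_0.2 = sum(int > 0.2),
      mz_diff_sd = if (n > 2) stats::sd(diff(sort(mz))) else 0,
      frags_per_2da = n / n_win,
      intensity_balance = intensity_balance(spec, balance_bins),
      entropy_mz = shannon_entropy(mz),
      entropy_int = shannon_entropy(int))
  } else {
    vals <- stats::setNames(rep(0, 12),
      c("n_peaks", "int_mean", "int_sum", "int_sd", "dot_mz_int", "n_gt_0.1",
        "n_gt_0.2", "mz_diff_sd", "frags_per_2da", "intensity_balance",
        "entropy_mz", "entropy_int"))
  }
  out <- c(vals, globals_of(spec))
  attr(out, "family") <- "handcrafted"
  out
}

#' 2D grid feature family
#'
#' Counts peaks on an `n_mz` x `n_int` lattice: equal-width m/z bins over
#' `[0, 1]` (normalized units; peaks above the precursor, mz > 1, are
#' clamped into the top bin) crossed with equal-width intensity bins over
#' `(0.05, 1]` (the post-denoising intensity range; lower values clamp into
#' the bottom bin). Cells are flattened m/z-major and named `C0`, `C1`, ...
#' so that with a single intensity bin `C0` is the lowest-m/z column.
#' Precursor m/z and collision energy are appended, giving
#' `n_mz * n_int + 2` values. The cell counts always sum to the retained
#' peak count; the (1, 1) grid in particular is just that count.
#'
#' @param spec a preprocessed `ms2_spectrum_norm`.
#' @param n_mz,n_int number of bins per axis, each in 1..20.
#' @param int_min lower edge of the intensity axis (default 0.05, the
#'   noise-filter cutoff).
#' @return Named numeric vector with `attr(, "family") = "grid2d"`.
#' @export
grid_features_2d <- function(spec, n_mz, n_int, int_min = 0.05) {
  stopifnot(n_mz >= 1, n_mz <= 20, n_int >= 1, n_int <= 20)
  counts <- matrix(0L, nrow = n_mz, ncol = n_int)
  pk <- spec$peaks
  if (nrow(pk)) {
    i_mz <- pmin(n_mz, pmax(1L, floor(pk[, "mz"] * n_mz) + 1L))
    h <- (1 - int_min) / n_int
    i_int <- pmin(n_int, pmax(1L, ceiling((pk[, "intensity"] - int_min) / h)))
    for (k in seq_len(nrow(pk)))
      counts[i_mz[k], i_int[k]] <- counts[i_mz[k], i_int[k]] + 1L
  }
  flat <- as.numeric(t(counts))  # m/z-major: all intensity bins of column 1 first
  names(flat) <- paste0("C", seq_along(flat) - 1L)
  out <- c(flat, globals_of(spec))
  attr(out, "family") <- "grid2d"
  out
}

#' 1D grid feature family
#'
#' Counts peaks in `n_int` intensity bins whose edges are geometrically
#' spaced from 0.05 to 1.0 (`edge_k = 0.05 * 20^(k / n_int)`), giving
#' narrower bins at low intensity where most retained fragments sit.
#' Precursor m/z and collision energy are appended: `n_int + 2` values.
#' Bin counts sum to the retained peak count for any `n_int`.
#'
#' @param spec a preprocessed `ms2_spectrum_norm`.
#' @param n_int number of intensity bins in 1..20.
#' @param int_min lower edge of the intensity axis (default 0.05).
#' @return Named numeric vector with `attr(, "family") = "grid1d"`.
#' @export
grid_features_1d <- function(spec, n_int, int_min = 0.05) {
  stopifnot(n_int >= 1, n_int <= 20)
  counts <- numeric(n_int)
  pk <- spec$peaks
  if (nrow(pk)) {
    # bin of intensity i: smallest k with i <= int_min * (1/int_min)^(k/n_int)
    k <- ceiling(n_int * log(pk[, "intensity"] / int_min) / log(1 / int_min))
    k <- pmin(n_int, pmax(1L, k))
    for (b in k) counts[b] <- counts[b] + 1
  }
  names(counts) <- paste0("B", seq_len(n_int) - 1L)
  out <- c(counts, globals_of(spec))
  attr(out, "family") <- "grid1d"
  out
}

#' Baseline feature: retained peak count
#'
#' The single-feature baseline the classifier is benchmarked against: the
#' number of peaks surviving preprocessing — identical to the (1, 1) grid
#' cell. No global descriptors are appended; the baseline model sees exactly
#' one feature.
#'
#' @param spec a preprocessed `ms2_spectrum_norm`.
#' @return Named numeric vector of length 1 with `attr(, "family") = "baseline"`.
#' @export
baseline_features <- function(spec) {
  out <- c(n_peaks = as.numeric(nrow(spec$peaks)))
  attr(out, "family") <- "baseline"
  out
}

#' Compute one spectrum's feature vector for a named family
#'
#' @param spec a preprocessed `ms2_spectrum_norm`.
#' @param family one of `"distance"`, `"handcrafted"`, `"combined"`
#'   (handcrafted + distance descriptors with the globals appended once),
#'   `"grid1d"`, `"grid2d"`, `"baseline"`.
#' @param n_mz,n_int grid dimensions (used by the grid families; defaults
#'   are the best-performing grids: 14 intensity bins in 1D, 19 x 1 in 2D).
#' @param balance_bins bins for the intensity balance descriptor.
#' @return Named numeric vector with a `family` attribute.
#' @export
featurize <- function(spec, family = c("handcrafted", "distance", "combined",
                                       "grid1d", "grid2d", "baseline"),
                      n_mz = 19, n_int = if (identical(family, "grid1d")) 14 else 1,
                      balance_bins = 10) {
  family <- match.arg(family)
  out <- switch(family,
    handcrafted = handcrafted_features(spec, balance_bins),
    distance = distance_features(spec),
    combined = {
      h <- handcrafted_features(spec, balance_bins)
      d <- distance_features(spec)
      v <- c(h[seq_len(length(h) - 2L)], d)
      attr(v, "family") <- "combined"
      v
    },
    grid1d = grid_features_1d(spec, n_int),
    grid2d = grid_features_2d(spec, n_mz, n_int),
    baseline = baseline_features(spec))
  out
}

#' Featurize a dataset of spectra
#'
#' Applies [featurize()] to every spectrum and stacks the results into a
#' feature matrix whose rows align with the input order (row names are the
#' spectrum ids). Labels travel alongside; unlabeled spectra carry `NA`.
#'
#' @inheritParams featurize
#' @param spectra list of preprocessed `ms2_spectrum_norm` objects.
#' @return List of class `ms2_features`: `features` (numeric matrix),
#'   `labels` (character, `NA` where unlabeled), `ids`, `family`.
#' @export
featurize_dataset <- function(spectra, family = "handcrafted",
                              n_mz = 19, n_int = if (identical(family, "grid1d")) 14 else 1,
                              balance_bins = 10) {
  rows <- lapply(spectra, featurize, family = family, n_mz = n_mz,
                 n_int = n_int, balance_bins = balance_bins)
  if (length(rows)) {
    feat <- do.call(rbind, rows)
  } else {
    template <- featurize(denoise_spectrum(normalize_spectrum(
      ms2_spectrum("template", 100, 0))), family = family,
      n_mz = n_mz, n_int = n_int, balance_bins = balance_bins)
    feat <- matrix(numeric(0), nrow = 0, ncol = length(template),
                   dimnames = list(NULL, names(template)))
  }
  ids <- vapply(spectra, function(s) s$id, character(1))
  rownames(feat) <- ids
  structure(list(features = feat,
                 labels = unname(spectrum_labels(spectra)),
                 ids = ids, family = family),
            class = "ms2_features")
}

#' @export
print.ms2_features <- function(x, ...) {
  cat(sprintf("<ms2_features>  %d spectra x %d '%s' features  (%d labeled)\n",
              nrow(x$features), ncol(x$features), x$family, sum(!is.na(x$labels))))
  invisible(x)
}

#' Write or read a feature matrix as CSV
#'
#' CSV with an `id` index column, one named column per feature, and a
#' `label` column (empty where unlabeled).
#' @param fset an `ms2_features` object from [featurize_dataset()].
#' @param path file path.
#' @export
write_features_csv <- function(fset, path) {
  df <- data.frame(id = fset$ids, fset$features,
                   label = ifelse(is.na(fset$labels), "", fset$labels),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @param family family tag to record on the read object.
#' @export
read_features_csv <- function(path, family = "handcrafted") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = c(id = "character"))
  lab <- as.character(df$label)
  lab[!nzchar(lab) | is.na(lab)] <- NA_character_
  feat <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  rownames(feat) <- df$id
  structure(list(features = feat, labels = lab, ids = df$id, family = family),
            class = "ms2_features")
}
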