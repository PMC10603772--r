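norm_spec <- function(mz, int, id = "f", precursor = 1, ce = 35) {
  # build an already-normalized spectrum directly (precursor 1 keeps mz as-is)
  s <- ms2_spectrum(id, precursor, ce, mz = mz * precursor, intensity = int)
  n <- normalize_spectrum(s)
  n$peaks[, "intensity"] <- int[order(mz)]  # intensities given as relative
  n
}

test_that("centroid matches its definition", {
  expect_equal(unname(compute_centroid(norm_spec(0.5, 1.0))), c(0.5, 1.0))
  expect_equal(unname(compute_centroid(norm_spec(c(0.2, 0.8), c(1, 1)))), c(0.5, 1.0))

  set.seed(21)
  for (i in 1:50) {
    sp <- random_norm_spectrum(n = sample(1:30, 1))
    if (!nrow(sp$peaks)) next
    pk <- sp$peaks
    expect_equal(unname(compute_centroid(sp)),
                 c(sum(pk[, 1] * pk[, 2]) / sum(pk[, 2]), mean(pk[, 2])),
                 tolerance = 1e-12)
  }
  expect_error(compute_centroid(normalize_spectrum(ms2_spectrum("e", 100, 10))),
               "empty")
})

test_that("distance features match a naive oracle and have the right shape", {
  sp1 <- norm_spec(0.4, 1.0)
  d1 <- distance_features(sp1)
  expect_length(d1, 10)
  expect_equal(unname(d1[1:8]), c(1, rep(0, 7)))  # a lone peak is its own centroid
  expect_identical(names(d1)[9:10], c("precursor_mz", "collision_energy"))

  set.seed(22)
  for (i in 1:50) {
    sp <- random_norm_spectrum(n = sample(0:30, 1))
    f <- distance_features(sp)
    expect_equal(unname(f[1:8]), naive_distance_stats(sp), tolerance = 1e-9)
    expect_true(f["d_min"] <= f["d_q1"] + 1e-12 && f["d_q1"] <= f["d_q2"] + 1e-12 &&
                f["d_q2"] <= f["d_q3"] + 1e-12 && f["d_q3"] <= f["d_max"] + 1e-12)
  }
})

test_that("shannon entropy follows the definition", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(numeric(0)), 0)
  expect_equal(shannon_entropy(c(0, 0)), 0)
  expect_error(shannon_entropy(c(1, -1)), "nonnegative")
  set.seed(23)
  for (i in 1:20) {
    v <- runif(30)
    expect_equal(shannon_entropy(v), naive_entropy(v), tolerance = 1e-12)
    expect_true(shannon_entropy(v) <= log(length(v)) + 1e-12)
  }
})

test_that("intensity balance separates first-bin mass from the rest", {
  # all intensity mass in the first of 10 bins spanning [0, max(mz)]
  low <- norm_spec(c(0.01, 0.05, 1.0), c(1, 0.5, 0))
  expect_equal(intensity_balance(low), -1.5)
  high <- norm_spec(c(0.5, 0.9, 1.0), c(0.3, 0.6, 1))
  expect_equal(intensity_balance(high), 1.9)
  set.seed(24)
  for (i in 1:50) {
    sp <- random_norm_spectrum(n = sample(0:25, 1))
    expect_equal(intensity_balance(sp), naive_balance(sp), tolerance = 1e-9)
  }
})

test_that("handcrafted features match a naive oracle", {
  f <- handcrafted_features(norm_spec(0.6, 1.0, precursor = 200))
  expect_length(f, 14)
  expect_equal(unname(f["dot_mz_int"]), 0.6)
  expect_equal(unname(f["n_gt_0.1"]), 1)
  expect_equal(unname(f["mz_diff_sd"]), 0)

  un <- handcrafted_features(norm_spec(seq(0.1, 0.9, length.out = 5), rep(1, 5)))
  expect_equal(unname(un["entropy_int"]), log(5))

  set.seed(25)
  for (i in 1:50) {
    sp <- random_norm_spectrum(n = sample(0:30, 1), precursor = runif(1, 100, 900))
    f <- handcrafted_features(sp)
    expect_equal(unname(f[1:12]), naive_handcrafted(sp), tolerance = 1e-9)
  }
})

test_that("grid features conserve peak counts and match naive binning", {
  set.seed(26)
  for (i in 1:50) {
    sp <- random_norm_spectrum(n = sample(0:30, 1))
    np <- nrow(sp$peaks)
    g11 <- grid_features_2d(sp, 1, 1)
    expect_length(g11, 3)
    expect_equal(unname(g11["C0"]), np)          # (1,1) cell is the peak count
    expect_equal(unname(g11["C0"]), unname(baseline_features(sp)),
                 ignore_attr = TRUE)

    dims <- matrix(sample(1:20, 6, replace = TRUE), ncol = 2)
    for (r in seq_len(nrow(dims))) {
      g <- grid_features_2d(sp, dims[r, 1], dims[r, 2])
      cells <- g[seq_len(length(g) - 2)]
      expect_equal(sum(cells), np)
      expect_equal(unname(cells), naive_grid2d(sp, dims[r, 1], dims[r, 2]),
                   tolerance = 1e-9)
    }
    for (b in sample(1:20, 3)) {
      g1 <- grid_features_1d(sp, b)
      expect_length(g1, b + 2)
      expect_equal(sum(g1[seq_len(b)]), np)
      expect_equal(unname(g1[seq_len(b)]), naive_grid1d(sp, b), tolerance = 1e-9)
    }
  }
})

test_that("feature vectors have the documented lengths and terminal globals", {
  set.seed(27)
  sp <- random_norm_spectrum(n = 15)
  lens <- c(handcrafted = 14, distance = 10, combined = 22, baseline = 1)
  for (fam in names(lens)) {
    f <- featurize(sp, fam)
    expect_length(f, lens[[fam]])
    if (fam != "baseline")
      expect_identical(utils::tail(names(f), 2), c("precursor_mz", "collision_energy"))
  }
  expect_length(featurize(sp, "grid1d", n_int = 14), 16)
  expect_length(featurize(sp, "grid2d", n_mz = 19, n_int = 1), 21)
})

test_that("features are set functions: permuting peaks changes nothing", {
  set.seed(28)
  for (i in 1:20) {
    sp <- random_norm_spectrum(n = 20)
    perm <- sp
    idx <- sample(nrow(sp$peaks))
    # rebuild from permuted raw peaks; constructor re-sorts
    rebuilt <- ms2_spectrum(sp$id, sp$precursor_mz, sp$collision_energy,
                            mz = sp$peaks[idx, "mz"], intensity = sp$peaks[idx, "intensity"])
    rebuilt <- structure(rebuilt, class = class(sp))
    for (fam in c("handcrafted", "distance", "grid2d"))
      expect_equal(featurize(rebuilt, fam), featurize(sp, fam))
  }
})

test_that("empty spectra yield all-zero descriptor rows, not errors", {
  e <- denoise_spectrum(normalize_spectrum(ms2_spectrum("e", 100, 10)))
  expect_equal(nrow(e$peaks), 0)
  expect_equal(unname(handcrafted_features(e)[1:12]), rep(0, 12))
  expect_equal(unname(distance_features(e)[1:8]), rep(0, 8))
  expect_equal(unname(baseline_features(e)), 0, ignore_attr = TRUE)
  expect_equal(sum(grid_features_2d(e, 5, 5)[1:25]), 0)
})

test_that("featurize_dataset rows equal single-spectrum featurization", {
  set.seed(29)
  spectra <- preprocess_spectra(generate_dataset(synthetic_config(12, seed = 29)))
  fs <- featurize_dataset(spectra, "handcrafted")
  expect_equal(dim(fs$features), c(12, 14))
  for (i in c(1, 5, 12))
    expect_equal(unname(fs$features[i, ]),
                 unname(featurize(spectra[[i]], "handcrafted")),
                 ignore_attr = TRUE)
  empty <- featurize_dataset(list(), "handcrafted")
  expect_equal(dim(empty$features), c(0, 14))

  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fs, path)
  back <- read_features_csv(path)
  expect_equal(back$features, fs$features, tolerance = 1e-9)
  expect_identical(back$labels, fs$labels)
})
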