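test_that("spearman dissimilarity has the defining matrix properties", {
  set.seed(401)
  x <- cbind(a = rnorm(30), b = rnorm(30))
  x <- cbind(x, c = -x[, "a"], d = x[, "b"]^3)  # monotone transform of b
  D <- spearman_dissimilarity(x)
  expect_equal(diag(D$D), rep(0, 4), ignore_attr = TRUE)
  expect_equal(D$D, t(D$D))
  expect_true(all(D$D >= 0 & D$D <= 1))
  expect_equal(D$D["a", "c"], 0)  # anti-correlation: |rho| = 1
  expect_equal(D$D["b", "d"], 0)  # rank correlation ignores monotone transforms

  xc <- cbind(x, e = rep(2, 30))
  expect_warning(Dc <- spearman_dissimilarity(xc), "constant")
  expect_equal(unname(Dc$D["e", "a"]), 1)
  expect_error(spearman_dissimilarity(x[1:2, ]), "3 rows")
})

test_that("peak count and distance count are fully correlated features", {
  pre <- preprocess_spectra(generate_dataset(synthetic_config(80, seed = 402)))
  comb <- featurize_dataset(pre, "combined")
  D <- spearman_dissimilarity(comb$features)
  expect_equal(unname(D$D["n_peaks", "d_count"]), 0)
  kept <- correlation_filter(D, 0.3)
  expect_false(all(c("n_peaks", "d_count") %in% kept))  # collapsed to one
  # the two global descriptors are independent of everything else
  expect_true(all(c("precursor_mz", "collision_energy") %in% kept))
})

test_that("the correlation filter keeps one representative per cluster", {
  set.seed(403)
  base <- rnorm(40)
  x <- cbind(f1 = base, f2 = base, f3 = base)
  suppressWarnings(D <- spearman_dissimilarity(x))
  expect_length(correlation_filter(D), 1)

  y <- cbind(u = c(rep(0, 20), rep(1, 20))[sample(40)], v = rnorm(40))
  Dy <- spearman_dissimilarity(y)
  if (Dy$D["u", "v"] >= 0.3) expect_setequal(correlation_filter(Dy), c("u", "v"))

  # representative choice is invariant to column order
  pre <- preprocess_spectra(generate_dataset(synthetic_config(60, seed = 404)))
  fm <- featurize_dataset(pre, "handcrafted")$features
  k1 <- correlation_filter(spearman_dissimilarity(fm), 0.3)
  k2 <- correlation_filter(spearman_dissimilarity(fm[, rev(colnames(fm))]), 0.3)
  expect_setequal(k1, k2)
})

test_that("RFECV keeps a planted informative feature and obeys the 1-SE rule", {
  set.seed(405)
  n <- 120
  y <- sample(rep(c("good", "poor"), c(53, 67)))
  recovered <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    x <- cbind(signal = ifelse(y == "good", 1, 0) + rnorm(n, 0, 0.4),
               matrix(rnorm(n * 5), n, 5,
                      dimnames = list(NULL, paste0("noise", 1:5))))
    sel <- rfecv_select(x, y, k = 5, hp = small_hp(100), seed = s)
    if ("signal" %in% sel$selected) recovered <- recovered + 1
    best <- max(sel$scores$mean_ap)
    se_at_best <- sel$scores$se_ap[which.max(sel$scores$mean_ap)]
    chosen <- sel$scores$mean_ap[sel$scores$size == sel$best_size]
    expect_gte(chosen, best - se_at_best - 1e-12)
  }
  expect_gte(recovered / 20, 0.95)
})

test_that("RFECV collapses identical features and rejects degenerate input", {
  set.seed(406)
  y <- sample(rep(c("good", "poor"), 30))
  base <- ifelse(y == "good", 1, 0) + rnorm(60, 0, 0.4)
  x <- cbind(a = base, b = base, c = base)
  sel <- rfecv_select(x, y, k = 5, hp = small_hp(50), seed = 1)
  expect_equal(sel$best_size, 1)
  expect_error(rfecv_select(x[, 1, drop = FALSE], y), "2 features")
  expect_error(rfecv_select(x, rep("good", 60)), "both classes")
})

test_that("the grid-bin search sweeps all combinations with valid metrics", {
  pre <- preprocess_spectra(generate_dataset(synthetic_config(80, seed = 407)))
  gs <- grid_bin_search(pre, n_mz = c(1, 4), n_int = c(1, 3), k = 3,
                        hp = small_hp(50), seed = 1)
  expect_equal(nrow(gs$grid2d), 4)
  expect_equal(nrow(gs$grid1d), 2)
  expect_true(all(gs$grid2d$roc_auc_mean >= 0 & gs$grid2d$roc_auc_mean <= 1))
  expect_true(all(gs$grid2d$log_loss_mean >= 0))
  expect_true(all(gs$grid2d$accuracy_sd >= 0))

  m <- grid_metric_matrix(gs, "roc_auc")
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["1", "3"],
               gs$grid2d$roc_auc_mean[gs$grid2d$n_mz == 1 & gs$grid2d$n_int == 3])

  # the (1,1) grid carries the same information as the baseline + globals
  cell11 <- featurize_dataset(pre, "grid2d", n_mz = 1, n_int = 1)
  bl <- featurize_dataset(pre, "baseline")
  expect_equal(unname(cell11$features[, "C0"]), unname(bl$features[, "n_peaks"]))
})
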