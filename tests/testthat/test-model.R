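# shared small labeled feature set
fset150 <- local({
  pre <- preprocess_spectra(generate_dataset(synthetic_config(150, seed = 301)))
  featurize_dataset(pre, "handcrafted")
})

test_that("the hyperparameter grid enumerates 108 candidates", {
  g <- ms2_hp_grid()
  expect_equal(nrow(g), 108)
  expect_equal(nrow(unique(g)), 108)
  expect_setequal(unique(g$n_estimators), c(50, 100, 200))
  expect_setequal(unique(g$min_samples_leaf), c(1, 2, 4))
})

test_that("stratified splitting reproduces the 949/450 partition", {
  labels <- rep(c("good", "poor"), c(615, 784))
  sp <- split_train_test(labels, test_fraction = 0.322, seed = 1)
  expect_length(sp$train, 949)
  expect_length(sp$test, 450)
  expect_equal(sum(labels[sp$train] == "good"), 417)
  expect_equal(sum(labels[sp$test] == "good"), 198)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))

  even <- split_train_test(rep(c("good", "poor"), each = 5),
                           test_fraction = 0.5, seed = 2)
  expect_length(even$train, 5)
  expect_length(even$test, 5)
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  labels <- rep(c("good", "poor"), c(417, 532))  # the 949-instance training set
  folds <- stratified_folds(labels, 10, seed = 3)
  sizes <- tabulate(folds, 10)
  expect_equal(sum(sizes), 949)
  expect_true(all(sizes %in% 94:95))
  expect_equal(sort(unique(folds)), 1:10)
  # most folds leave exactly 854 instances for fitting
  expect_equal(as.integer(names(which.max(table(949 - sizes)))), 854)
  # class proportions preserved within one observation
  for (f in 1:10) {
    g <- sum(labels[folds == f] == "good")
    expect_true(abs(g - 417 / 10) <= 1)
  }
  expect_error(stratified_folds(rep(c("good", "poor"), c(5, 100)), 10),
               "at least k")
})

test_that("metrics agree with independently computed reference values", {
  # fixture scored once with scikit-learn's average_precision_score,
  # roc_auc_score and log_loss (values frozen below)
  prob <- c(0.867, 0.156, 0.508, 0.867, 0.059, 0.087, 0.199, 0.437, 0.565,
            0.334, 0.483, 0.859, 0.839, 0.166, 0.591, 0.208, 0.601, 0.534,
            0.22, 0.012)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 0, 0, 1, 0, 1, 0, 0, 1, 0)
  lab <- ifelse(y == 1, "good", "poor")
  expect_equal(average_precision(lab, prob), 0.594117148283815, tolerance = 1e-12)
  expect_equal(roc_auc(lab, prob), 0.5555555555555556, tolerance = 1e-12)
  expect_equal(log_loss(lab, prob), 0.852712901882604, tolerance = 1e-12)

  tm <- thresholded_metrics(lab, prob, 0.5)
  expect_equal(sum(tm$confusion), 20)
  expect_equal(tm$accuracy, (tm$confusion["tp"] + tm$confusion["tn"]) / 20,
               ignore_attr = TRUE)
})

test_that("threshold optimization matches brute force and favors precision", {
  # perfectly separated scores: optimum at the lowest good probability
  sep <- optimize_threshold(c(0.1, 0.9), c("poor", "good"), beta = 0.5)
  expect_equal(sep$threshold, 0.9)
  expect_equal(sep$f_beta, 1)

  set.seed(304)
  for (i in 1:20) {
    n <- 25
    lab <- sample(c("good", "poor"), n, replace = TRUE, prob = c(0.45, 0.55))
    if (length(unique(lab)) < 2) next
    prob <- round(pmin(pmax(
      ifelse(lab == "good", 0.6, 0.35) + rnorm(n, 0, 0.25), 0), 1), 2)
    for (beta in c(0.5, 1)) {
      got <- optimize_threshold(prob, lab, beta)
      ref <- naive_best_threshold(prob, lab, beta)
      expect_equal(got$threshold, ref$threshold)
      expect_equal(got$f_beta, ref$f_beta, tolerance = 1e-12)
    }
    # beta = 0.5 weights precision harder: never a lower threshold than beta = 1
    expect_gte(optimize_threshold(prob, lab, 0.5)$threshold,
               optimize_threshold(prob, lab, 1)$threshold)
    # beta -> 0 degenerates to precision maximization (highest F at max precision)
    t0 <- optimize_threshold(prob, lab, 1e-6)
    prec_at <- function(t) thresholded_metrics(lab, prob, t)$precision
    precs <- vapply(unique(c(0, prob, 1)), prec_at, numeric(1))
    expect_equal(prec_at(t0$threshold), max(precs, na.rm = TRUE), tolerance = 1e-9)
  }
})

test_that("fitting is deterministic and separable data is learned", {
  x <- fset150$features
  y <- fset150$labels
  m1 <- ms2rf(x, y, seed = 7)
  m2 <- ms2rf(x, y, seed = 7)
  expect_identical(predict(m1, x), predict(m2, x))
  # synthetic classes are near-separable; training accuracy is high
  acc <- mean(as.character(predict(m1, x, type = "response")) == y)
  expect_gte(acc, 0.99)
  expect_error(ms2rf(x, rep("good", nrow(x))), "both classes")
  xna <- x; xna[1, 1] <- NA
  expect_error(ms2rf(xna, y), "finite")
})

test_that("the scaler is fitted on training rows only", {
  x <- fset150$features
  m <- ms2rf(x, fset150$labels, seed = 7)
  expect_equal(m$scaler$center, colMeans(x))
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  expect_equal(m$scaler$scale, sds)
  # predicting on new rows cannot alter the stored scaler
  set.seed(305)
  p <- predict(m, x[sample(150, 30), ])
  expect_equal(m$scaler$center, colMeans(x))
})

test_that("prediction refuses mismatched feature names", {
  m <- ms2rf(fset150$features, fset150$labels, seed = 7)
  bad <- fset150$features
  colnames(bad)[1] <- "mystery"
  expect_error(predict(m, bad), "feature names")
  reordered <- fset150$features[, rev(colnames(fset150$features))]
  expect_error(predict(m, reordered), "feature names")
})

test_that("tuning over a grid picks a candidate and records scores", {
  grid <- expand.grid(n_estimators = c(50L, 100L), max_depth = c(NA_integer_, 10L),
                      min_samples_split = 2L, min_samples_leaf = 1L,
                      KEEP.OUT.ATTRS = FALSE)
  m <- ms2rf(fset150$features, fset150$labels, hp_grid = grid, cv_folds = 3,
             seed = 9)
  expect_equal(nrow(m$tuning), 4)
  expect_true(all(m$tuning$cv_average_precision >= 0 &
                  m$tuning$cv_average_precision <= 1))
  best <- m$tuning[which.max(m$tuning$cv_average_precision), ]
  expect_equal(m$hyperparameters$n_estimators, best$n_estimators)
})

test_that("cross-validation folds partition the data and report all metrics", {
  cv <- cross_validate(fset150, k = 5, hp = small_hp(), seed = 11)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(sum(cv$per_fold$n_predict), 150)
  expect_true(all(cv$per_fold$n_fit + cv$per_fold$n_predict == 150))
  expect_true(all(is.finite(unlist(cv$per_fold[, -1]))))
  expect_true(all(cv$oof_prob >= 0 & cv$oof_prob <= 1))
  expect_named(cv$mean, c("accuracy", "average_precision", "roc_auc", "log_loss"))
})

test_that("impurity importances are normalized and rank signal above noise", {
  set.seed(306)
  n <- 200
  y <- sample(c("good", "poor"), n, replace = TRUE)
  x <- cbind(signal = ifelse(y == "good", 1, 0) + rnorm(n, 0, 0.3),
             noise1 = rnorm(n), noise2 = rnorm(n), constant = rep(1, n))
  wins <- 0
  for (s in 1:20) {
    m <- ms2rf(x, y, seed = s)
    imp <- feature_importance(m)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(imp >= 0))
    expect_lt(imp["constant"], 0.01)
    if (imp["signal"] > max(imp[c("noise1", "noise2")])) wins <- wins + 1
  }
  expect_gte(wins / 20, 0.95)
})

test_that("evaluation respects the stored threshold and recall is monotone", {
  split <- split_train_test(fset150, 0.3, seed = 13)
  m <- ms2rf(split$train, seed = 13)
  ev <- evaluate(m, split$test)
  expect_equal(sum(ev$confusion), ev$n)
  expect_true(all(unlist(ev[c("accuracy", "average_precision", "roc_auc")]) <= 1))
  recalls <- vapply(seq(0, 1, 0.1), function(t)
    thresholded_metrics(split$test$labels, ev$prob, t)$recall, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
  # perfect predictions give accuracy 1 and an empty error count
  perfect <- thresholded_metrics(c("good", "poor"), c(0.9, 0.1), 0.5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$confusion[c("fp", "fn")]), c(0, 0))
})
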