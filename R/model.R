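#' Random-forest hyperparameter grid
#'
#' The exhaustive tuning grid for [ms2rf()]: 3 forest sizes x 4 depth
#' limits x 3 split minima x 3 leaf minima = 108 candidates. `max_depth`
#' `NA` means unlimited depth.
#'
#' @return data.frame with columns `n_estimators`, `max_depth`,
#'   `min_samples_split`, `min_samples_leaf`.
#' @export
ms2_hp_grid <- function() {
  expand.grid(n_estimators = c(50L, 100L, 200L),
              max_depth = c(NA_integer_, 10L, 20L, 30L),
              min_samples_split = c(2L, 5L, 10L),
              min_samples_leaf = c(1L, 2L, 4L),
              KEEP.OUT.ATTRS = FALSE)
}

default_hp <- function()
  data.frame(n_estimators = 200L, max_depth = NA_integer_,
             min_samples_split = 2L, min_samples_leaf = 1L)

fit_forest <- function(x, y, hp, seed, num_threads = 1L) {
  d <- data.frame(..y = y, x, check.names = FALSE)
  tab <- table(y)
  cw <- stats::setNames(as.numeric(sum(tab) / (length(tab) * tab)), names(tab))
  ranger::ranger(
    dependent.variable.name = "..y", data = d,
    num.trees = hp$n_estimators,
    max.depth = if (is.na(hp$max_depth)) 0 else hp$max_depth,
    min.node.size = hp$min_samples_split,
    min.bucket = hp$min_samples_leaf,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    probability = TRUE, replace = TRUE,
    class.weights = unname(cw[levels(y)]),  # "balanced" weights, level order
    importance = "impurity",
    seed = seed, num.threads = num_threads)
}

make_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1  # constant columns pass through
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler)
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")

as_label_factor <- function(labels) {
  l <- as.character(labels)
  if (anyNA(l)) stop("all observations must be labeled")
  if (!all(l %in% c("good", "poor"))) stop("labels must be 'good'/'poor'")
  factor(l, levels = c("good", "poor"))
}

check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  if (!all(is.finite(x))) stop("feature matrix must be finite (no NaN/NA/Inf)")
  y <- as_label_factor(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  list(x = x, y = y)
}

#' Fit a spectrum-quality random forest
#'
#' The package's central fitting function. Trains a random forest (balanced
#' class weights, bootstrap resampling, sqrt feature subsampling, fixed
#' seed) to classify spectra as providing good or poor diagnostic
#' information from a feature matrix produced by [featurize_dataset()].
#' Columns are centered and scaled with training-set statistics; the scaler
#' is stored on the model and applied to all new data. When a
#' hyperparameter grid is supplied, every grid point is scored by
#' stratified k-fold cross-validated average precision and the best point
#' is refit on all training data (ties resolved to the first grid row).
#'
#' "good" is the positive class throughout; the stored decision threshold
#' (default 0.5, tune with [optimize_threshold()] / [set_threshold()])
#' converts predicted probabilities to labels via `prob >= threshold`.
#'
#' @param x feature matrix with named columns, or an `ms2_features` object
#'   (in which case `y` is taken from its labels).
#' @param y labels (`"good"`/`"poor"`), one per row of `x`.
#' @param hp_grid `NULL` for fixed default hyperparameters (200 trees,
#'   unlimited depth, split minimum 2, leaf minimum 1), or a data.frame in
#'   the format of [ms2_hp_grid()] to tune over.
#' @param cv_folds folds for the tuning cross-validation.
#' @param seed integer seed controlling fold assignment and forest growth.
#' @param num_threads threads for the forest backend (1 keeps runs
#'   bit-reproducible).
#' @param ... passed between methods.
#' @return An object of class `ms2rf`: list with `forest` (ranger fit),
#'   `scaler`, `threshold`, `feature_names`, `hyperparameters`, `tuning`
#'   (per-grid-point CV scores, or `NULL`), `levels`, `seed`.
#' @seealso [predict.ms2rf()], [evaluate()], [feature_importance()],
#'   [cross_validate()]
#' @examples
#' spectra <- preprocess_spectra(generate_dataset(synthetic_config(120, seed = 3)))
#' fs <- featurize_dataset(spectra, "handcrafted")
#' fit <- ms2rf(fs, seed = 3)
#' fit
#' @export
ms2rf <- function(x, ...) UseMethod("ms2rf")

#' @rdname ms2rf
#' @export
ms2rf.ms2_features <- function(x, y = x$labels, ...) ms2rf(x$features, y, ...)

#' @rdname ms2rf
#' @export
ms2rf.default <- function(x, y, hp_grid = NULL, cv_folds = 10, seed = 1L,
                          num_threads = 1L, ...) {
  xy <- check_xy(x, y)
  x <- xy$x; y <- xy$y
  scaler <- make_scaler(x)
  xs <- apply_scaler(x, scaler)

  tuning <- NULL
  hp <- default_hp()
  if (!is.null(hp_grid)) {
    stopifnot(is.data.frame(hp_grid),
              all(c("n_estimators", "max_depth", "min_samples_split",
                    "min_samples_leaf") %in% names(hp_grid)))
    folds <- stratified_folds(y, cv_folds, seed = seed)
    score <- numeric(nrow(hp_grid))
    for (g in seq_len(nrow(hp_grid))) {
      ap <- numeric(cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        sc <- make_scaler(x[tr, , drop = FALSE])
        fit <- fit_forest(apply_scaler(x[tr, , drop = FALSE], sc), y[tr],
                          hp_grid[g, ], seed = seed + f, num_threads = num_threads)
        p <- predict(fit, data.frame(apply_scaler(x[!tr, , drop = FALSE], sc),
                                     check.names = FALSE),
                     num.threads = num_threads)$predictions[, "good"]
        ap[f] <- average_precision(y[!tr], p)
      }
      score[g] <- mean(ap)
    }
    tuning <- cbind(hp_grid, cv_average_precision = score)
    hp <- hp_grid[which.max(score), , drop = FALSE]
  }

  forest <- fit_forest(xs, y, hp, seed = seed, num_threads = num_threads)
  structure(list(forest = forest, scaler = scaler, threshold = 0.5,
                 feature_names = colnames(x),
                 hyperparameters = as.list(hp), tuning = tuning,
                 levels = levels(y), seed = as.integer(seed),
                 n_train = nrow(x)),
            class = "ms2rf")
}

#' Predict spectrum quality with a fitted model
#'
#' Applies the stored column scaler, queries the forest for the probability
#' of the good class, and (for `type = "response"`) thresholds it at the
#' model's stored cutoff. Column names of `newdata` must match the training
#' feature names exactly and in order; a mismatch is a hard error rather
#' than a silent reorder.
#'
#' @param object an [ms2rf()] model.
#' @param newdata feature matrix or `ms2_features` object.
#' @param type `"prob"` for probabilities of good, `"response"` for labels.
#' @param ... unused.
#' @return Numeric vector of probabilities, or factor of labels.
#' @export
predict.ms2rf <- function(object, newdata, type = c("prob", "response"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ms2_features")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$feature_names))
    stop("feature names of newdata do not match the model (expected: ",
         paste(object$feature_names, collapse = ", "), ")")
  xs <- apply_scaler(newdata, object$scaler)
  p <- predict(object$forest, data.frame(xs, check.names = FALSE),
               num.threads = 1L)$predictions[, "good"]
  names(p) <- rownames(newdata)
  if (type == "prob") return(p)
  factor(ifelse(p >= object$threshold, "good", "poor"), levels = object$levels)
}

#' @export
print.ms2rf <- function(x, ...) {
  hp <- x$hyperparameters
  cat("<ms2rf> spectrum-quality random forest\n")
  cat(sprintf("  %d features, %d training spectra, positive class 'good'\n",
              length(x$feature_names), x$n_train))
  cat(sprintf("  trees %d, max depth %s, min split %d, min leaf %d%s\n",
              hp$n_estimators, ifelse(is.na(hp$max_depth), "unlimited",
                                      hp$max_depth),
              hp$min_samples_split, hp$min_samples_leaf,
              if (!is.null(x$tuning)) sprintf(" (tuned over %d candidates)",
                                              nrow(x$tuning)) else ""))
  cat(sprintf("  decision threshold %.3f, OOB prediction error %.4f\n",
              x$threshold, x$forest$prediction.error))
  invisible(x)
}

#' @export
summary.ms2rf <- function(object, ...) {
  print(object)
  cat("\nTop feature importances (impurity-based, normalized):\n")
  imp <- sort(feature_importance(object), decreasing = TRUE)
  print(round(utils::head(imp, 10), 4))
  invisible(object)
}

#' Impurity-based feature importance
#'
#' Gini-impurity importances from the forest, normalized to sum to 1 and
#' aligned with the model's feature names.
#'
#' @param model a fitted [ms2rf()] model.
#' @return Named nonnegative numeric vector summing to 1.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "ms2rf"))
  imp <- model$forest$variable.importance[model$feature_names]
  imp <- pmax(imp, 0)
  imp / sum(imp)
}

#' @export
plot.ms2rf <- function(x, n = 20, ...) {
  imp <- sort(feature_importance(x), decreasing = TRUE)
  imp <- utils::head(imp, n)
  op <- graphics::par(mar = c(4, 8, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(imp), horiz = TRUE, las = 1,
                    xlab = "normalized impurity importance",
                    main = "ms2rf feature importance", ...)
  invisible(x)
}

#' Set the decision threshold on a fitted model
#'
#' @param model an [ms2rf()] model.
#' @param threshold probability cutoff in `[0, 1]`.
#' @return The model with the stored threshold replaced.
#' @export
set_threshold <- function(model, threshold) {
  stopifnot(inherits(model, "ms2rf"), threshold >= 0, threshold <= 1)
  model$threshold <- threshold
  model
}

#' Stratified fold assignment
#'
#' Assigns observations to `k` cross-validation folds preserving class
#' proportions, balancing fold sizes so that no two folds differ by more
#' than one observation overall.
#'
#' @param y label vector.
#' @param k number of folds.
#' @param seed RNG seed for the within-class shuffle.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  if (min(table(y)) < k) stop("each class must have at least k observations")
  set.seed(seed)
  folds <- integer(length(y))
  totals <- numeric(k)
  for (cl in names(sort(table(y), decreasing = TRUE))) {
    idx <- sample(which(y == cl))
    base <- length(idx) %/% k
    rem <- length(idx) %% k
    sizes <- rep(base, k)
    if (rem) sizes[order(totals, seq_len(k))[seq_len(rem)]] <- base + 1L
    folds[idx] <- rep.int(seq_len(k), sizes)
    totals <- totals + sizes
  }
  folds
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into disjoint training and testing parts. The
#' test set holds `round(test_fraction * n)` observations, allocated across
#' classes by largest fractional remainder, so class proportions are
#' preserved to within one observation per class.
#'
#' @param x a list of labeled spectra, an `ms2_features` object, or a label
#'   vector.
#' @param test_fraction fraction held out for testing (default 0.322,
#'   giving 949 train / 450 test on a 1399-spectrum dataset).
#' @param seed RNG seed.
#' @return List with elements `train` and `test`, each the same type as
#'   `x` (for a label vector, integer index vectors are returned).
#' @export
split_train_test <- function(x, test_fraction = 0.322, seed = 1L) {
  labels <- if (inherits(x, "ms2_features")) x$labels
  else if (is.list(x)) unname(spectrum_labels(x))
  else as.character(x)
  if (anyNA(labels)) stop("all observations must be labeled for splitting")
  set.seed(seed)
  classes <- sort(unique(labels))
  n_cl <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  quota <- test_fraction * n_cl
  n_test_cl <- floor(quota)
  # distribute the remaining test slots by largest fractional remainder
  extra <- round(test_fraction * length(labels)) - sum(n_test_cl)
  if (extra > 0) {
    ord <- order(-(quota - n_test_cl), -n_cl, classes)
    n_test_cl[ord[seq_len(extra)]] <- n_test_cl[ord[seq_len(extra)]] + 1L
  }
  if (any(n_test_cl < 1) || any(n_test_cl >= n_cl))
    stop("a class is too small to stratify at this test fraction")
  test_idx <- unlist(lapply(seq_along(classes), function(i)
    sample(which(labels == classes[i]), n_test_cl[i])))
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labels), test_idx)
  subset_ds <- function(i) {
    if (inherits(x, "ms2_features"))
      structure(list(features = x$features[i, , drop = FALSE],
                     labels = x$labels[i], ids = x$ids[i], family = x$family),
                class = "ms2_features")
    else if (is.list(x)) x[i]
    else i
  }
  list(train = subset_ds(train_idx), test = subset_ds(test_idx))
}

#' Stratified k-fold cross-validation of the spectrum-quality forest
#'
#' Fits one forest per fold on the remaining k-1 folds (scaler refit on the
#' fitting rows only) and evaluates on the held-out fold. Reports the four
#' validation metrics (accuracy at threshold 0.5, average precision,
#' ROC AUC, log loss) per fold and their mean and standard deviation, plus
#' the out-of-fold probabilities (useful for leakage-free threshold
#' tuning).
#'
#' @inheritParams ms2rf.default
#' @param k number of folds.
#' @param hp single-row hyperparameter data.frame (default: fixed defaults).
#' @return Object of class `ms2_cv`: list with `per_fold` (data.frame),
#'   `mean`, `sd`, `folds` (fold ids), `oof_prob`, `labels`.
#' @export
cross_validate <- function(x, y = NULL, k = 10, hp = default_hp(),
                           seed = 1L, num_threads = 1L) {
  if (inherits(x, "ms2_features")) { if (is.null(y)) y <- x$labels; x <- x$features }
  xy <- check_xy(x, y)
  x <- xy$x; y <- xy$y
  folds <- stratified_folds(y, k, seed = seed)
  per_fold <- data.frame(fold = seq_len(k), n_fit = NA_real_, n_predict = NA_real_,
                         accuracy = NA_real_, average_precision = NA_real_,
                         roc_auc = NA_real_, log_loss = NA_real_)
  oof <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- make_scaler(x[tr, , drop = FALSE])
    fit <- fit_forest(apply_scaler(x[tr, , drop = FALSE], sc), y[tr], hp,
                      seed = seed + f, num_threads = num_threads)
    p <- predict(fit, data.frame(apply_scaler(x[!tr, , drop = FALSE], sc),
                                 check.names = FALSE),
                 num.threads = num_threads)$predictions[, "good"]
    oof[!tr] <- p
    tm <- thresholded_metrics(y[!tr], p, 0.5)
    per_fold[f, -1] <- c(sum(tr), sum(!tr), tm$accuracy,
                         average_precision(y[!tr], p),
                         roc_auc(y[!tr], p), log_loss(y[!tr], p))
  }
  metric_cols <- c("accuracy", "average_precision", "roc_auc", "log_loss")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2, stats::sd),
                 folds = folds, oof_prob = oof, labels = as.character(y)),
            class = "ms2_cv")
}

#' @export
print.ms2_cv <- function(x, ...) {
  cat(sprintf("<ms2_cv> %d-fold stratified cross-validation, n = %d\n",
              nrow(x$per_fold), length(x$folds)))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}

#' Precision-favoring decision-threshold optimization
#'
#' Evaluates the F-beta score of the good-vs-poor decision at every
#' distinct predicted probability (plus the boundary cutoffs 0 and 1) and
#' returns the cutoff maximizing it. Predictions use `prob >= threshold`;
#' ties are broken toward the higher threshold, i.e. toward precision.
#' `beta = 0.5` weights precision twice as heavily as recall; as
#' `beta -> 0` the criterion degenerates to precision alone.
#'
#' @param prob predicted probabilities of good.
#' @param labels true labels (`"good"`/`"poor"`), both classes present.
#' @param beta F-beta trade-off parameter (default 0.5).
#' @return List with `threshold`, `f_beta`, and `search` (data.frame of all
#'   candidate cutoffs with precision, recall and F-beta).
#' @export
optimize_threshold <- function(prob, labels, beta = 0.5) {
  y <- as_good(labels)
  if (!any(y) || all(y)) stop("both classes required to optimize a threshold")
  stopifnot(all(prob >= 0 & prob <= 1), beta > 0)
  cand <- sort(unique(c(0, prob, 1)))
  res <- vapply(cand, function(t) {
    tm <- thresholded_metrics(labels, prob, t)
    c(precision = tm$precision, recall = tm$recall,
      f_beta = f_beta_score(tm$precision, tm$recall, beta))
  }, numeric(3))
  search <- data.frame(threshold = cand, t(res))
  best <- max(search$f_beta)
  idx <- max(which(search$f_beta >= best - 1e-12))  # ties -> higher threshold
  list(threshold = search$threshold[idx], f_beta = search$f_beta[idx],
       search = search)
}

#' Evaluate a fitted model on labeled data
#'
#' Applies the stored scaler and decision threshold and reports accuracy,
#' precision, recall and the confusion matrix at that threshold, alongside
#' the threshold-free metrics (average precision, ROC AUC, log loss)
#' computed from the raw probabilities.
#'
#' @param model a fitted [ms2rf()].
#' @param x feature matrix or `ms2_features` (names must match training).
#' @param y true labels; defaults to the labels of an `ms2_features` input.
#' @return Object of class `ms2_eval`: list of metrics, `confusion`,
#'   `threshold`, `n`, and the per-spectrum `prob`.
#' @export
evaluate <- function(model, x, y = NULL) {
  stopifnot(inherits(model, "ms2rf"))
  if (inherits(x, "ms2_features")) { if (is.null(y)) y <- x$labels; x <- x$features }
  y <- as_label_factor(y)
  p <- predict(model, x, type = "prob")
  tm <- thresholded_metrics(y, p, model$threshold)
  structure(list(accuracy = tm$accuracy, precision = tm$precision,
                 recall = tm$recall,
                 average_precision = average_precision(y, p),
                 roc_auc = roc_auc(y, p), log_loss = log_loss(y, p),
                 confusion = tm$confusion, threshold = model$threshold,
                 n = length(y), prob = p),
            class = "ms2_eval")
}

#' @export
print.ms2_eval <- function(x, ...) {
  cat(sprintf("<ms2_eval> n = %d, threshold = %.3f\n", x$n, x$threshold))
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f\n",
              x$accuracy, x$precision, x$recall))
  cat(sprintf("  average precision %.3f  ROC AUC %.3f  log loss %.3f\n",
              x$average_precision, x$roc_auc, x$log_loss))
  cm <- x$confusion
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              cm["tp"], cm["fp"], cm["tn"], cm["fn"]))
  invisible(x)
}
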