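#' Spearman dissimilarity between features
#'
#' Pairwise feature dissimilarity `D = 1 - |rho|`, where `rho` is the
#' Spearman rank correlation between feature columns: 0 means fully
#' (anti-)correlated, 1 means rank-uncorrelated. Constant columns have no
#' defined rank correlation; their `rho` is set to 0 (`D = 1`) with a
#' warning.
#'
#' @param x numeric feature matrix (>= 3 rows, >= 2 named columns).
#' @return Object of class `ms2_dissimilarity`: list with `D` (symmetric
#'   matrix, zero diagonal) and `names`.
#' @export
spearman_dissimilarity <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("at least 3 rows required for rank correlation")
  if (ncol(x) < 2) stop("at least 2 features required")
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant feature column(s); their correlations set to 0: ",
            paste(colnames(x)[apply(x, 2, function(v) stats::sd(v) == 0)],
                  collapse = ", "))
    rho[is.na(rho)] <- 0
  }
  D <- 1 - abs(rho)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  stopifnot(all(D >= -1e-12 & D <= 1 + 1e-12))
  D[D < 0] <- 0; D[D > 1] <- 1
  structure(list(D = D, names = colnames(x)), class = "ms2_dissimilarity")
}

#' @export
print.ms2_dissimilarity <- function(x, ...) {
  cat(sprintf("<ms2_dissimilarity> %d features, D = 1 - |spearman rho|\n",
              length(x$names)))
  invisible(x)
}

#' Collapse correlated features by dissimilarity clustering
#'
#' Average-linkage hierarchical clustering on the Spearman dissimilarity,
#' cut at height `cutoff` (default 0.3: features with dissimilarity below
#' it end up in the same cluster and are considered redundant). One
#' representative is kept per cluster: the member with the highest mean
#' dissimilarity to all features outside its cluster (i.e. the member
#' carrying the most information not already represented elsewhere), ties
#' broken lexicographically by name.
#'
#' @param D an `ms2_dissimilarity` from [spearman_dissimilarity()].
#' @param cutoff tree-cut height; features at dissimilarity >= cutoff are
#'   treated as uncorrelated.
#' @return Character vector of selected feature names (original column
#'   order).
#' @export
correlation_filter <- function(D, cutoff = 0.3) {
  stopifnot(inherits(D, "ms2_dissimilarity"))
  hc <- stats::hclust(stats::as.dist(D$D), method = "average")
  cl <- stats::cutree(hc, h = cutoff)
  keep <- character(0)
  for (k in unique(cl)) {
    members <- D$names[cl == k]
    outside <- D$names[cl != k]
    score <- if (length(outside))
      rowMeans(D$D[members, outside, drop = FALSE])
    else stats::setNames(rep(0, length(members)), members)
    best <- max(score)
    cand <- sort(names(score)[score >= best - 1e-12])
    keep <- c(keep, cand[1])
  }
  D$names[D$names %in% keep]
}

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' Starting from the full feature set, repeatedly scores the current subset
#' by stratified k-fold cross-validated average precision, fits a forest on
#' all rows, and drops the feature with the lowest impurity importance
#' (step size 1) until one feature remains. The returned subset is the
#' smallest one whose mean CV score is within one standard error of the
#' best subset's score (1-SE parsimony rule).
#'
#' @param x labeled feature matrix with named columns (>= 2 features).
#' @param y labels (`"good"`/`"poor"`).
#' @param k CV folds.
#' @param hp single-row hyperparameter data.frame for the forests.
#' @param seed RNG seed.
#' @param num_threads forest threads.
#' @return List with `selected` (feature names, original order), `scores`
#'   (data.frame: subset size, mean and SE of CV average precision, and the
#'   feature dropped after scoring), and `best_size`.
#' @export
rfecv_select <- function(x, y, k = 10, hp = default_hp(), seed = 1L,
                         num_threads = 1L) {
  xy <- check_xy(x, y)
  x <- xy$x; y <- xy$y
  if (ncol(x) < 2) stop("at least 2 features required")
  current <- colnames(x)
  sizes <- integer(0); means <- numeric(0); ses <- numeric(0)
  dropped <- character(0); subsets <- list()
  folds <- stratified_folds(y, k, seed = seed)
  while (length(current) >= 1) {
    ap <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      sc <- make_scaler(x[tr, current, drop = FALSE])
      fit <- fit_forest(apply_scaler(x[tr, current, drop = FALSE], sc), y[tr],
                        hp, seed = seed + f, num_threads = num_threads)
      p <- predict(fit, data.frame(apply_scaler(x[!tr, current, drop = FALSE], sc),
                                   check.names = FALSE),
                   num.threads = num_threads)$predictions[, "good"]
      ap[f] <- average_precision(y[!tr], p)
    }
    sizes <- c(sizes, length(current))
    means <- c(means, mean(ap))
    ses <- c(ses, stats::sd(ap) / sqrt(k))
    subsets[[length(subsets) + 1L]] <- current
    if (length(current) == 1) break
    sc <- make_scaler(x[, current, drop = FALSE])
    full <- fit_forest(apply_scaler(x[, current, drop = FALSE], sc), y, hp,
                       seed = seed, num_threads = num_threads)
    imp <- full$variable.importance[current]
    worst <- names(which.min(imp))
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
  best <- which.max(means)
  ok <- which(means >= means[best] - ses[best])
  pick <- ok[which.min(sizes[ok])]  # smallest subset within 1 SE of the best
  list(selected = colnames(x)[colnames(x) %in% subsets[[pick]]],
       scores = data.frame(size = sizes, mean_ap = means, se_ap = ses,
                           dropped_next = c(dropped, NA_character_)),
       best_size = sizes[pick])
}

#' Grid-bin hyperparameter search for the grid feature families
#'
#' Evaluates every combination of m/z and intensity bin counts for the 2D
#' grid representation (and, analogously, every bin count for the 1D
#' geometric-intensity grid) by stratified k-fold cross-validation of the
#' spectrum-quality forest, recording mean and standard deviation of the
#' four validation metrics per combination.
#'
#' @param spectra list of labeled, preprocessed `ms2_spectrum_norm` objects.
#' @param n_mz,n_int integer vectors of bin counts to sweep (each within
#'   1..20).
#' @param include_1d also sweep the 1D grid over `n_int`.
#' @param k CV folds.
#' @param hp single-row hyperparameter data.frame for the forests.
#' @param seed RNG seed.
#' @param num_threads forest threads.
#' @return List of class `ms2_grid_search` with data.frames `grid2d`
#'   (columns `n_mz`, `n_int`, `<metric>_mean`, `<metric>_sd`) and `grid1d`
#'   (or `NULL`).
#' @export
grid_bin_search <- function(spectra, n_mz = 1:20, n_int = 1:20,
                            include_1d = TRUE, k = 10, hp = default_hp(),
                            seed = 1L, num_threads = 1L) {
  stopifnot(all(n_mz >= 1 & n_mz <= 20), all(n_int >= 1 & n_int <= 20))
  labels <- unname(spectrum_labels(spectra))
  metric_cols <- c("accuracy", "average_precision", "roc_auc", "log_loss")
  cv_row <- function(fs) {
    cv <- cross_validate(fs$features, labels, k = k, hp = hp, seed = seed,
                         num_threads = num_threads)
    stats::setNames(c(cv$mean, cv$sd),
                    c(paste0(metric_cols, "_mean"), paste0(metric_cols, "_sd")))
  }
  pairs <- expand.grid(n_mz = n_mz, n_int = n_int, KEEP.OUT.ATTRS = FALSE)
  res2 <- t(vapply(seq_len(nrow(pairs)), function(i) {
    cv_row(featurize_dataset(spectra, "grid2d",
                             n_mz = pairs$n_mz[i], n_int = pairs$n_int[i]))
  }, numeric(8)))
  grid2d <- cbind(pairs, as.data.frame(res2))
  grid1d <- NULL
  if (include_1d) {
    res1 <- t(vapply(n_int, function(b) {
      cv_row(featurize_dataset(spectra, "grid1d", n_int = b))
    }, numeric(8)))
    grid1d <- cbind(data.frame(n_int = n_int), as.data.frame(res1))
  }
  structure(list(grid2d = grid2d, grid1d = grid1d), class = "ms2_grid_search")
}

#' @export
print.ms2_grid_search <- function(x, ...) {
  cat(sprintf("<ms2_grid_search> %d 2D combinations%s\n", nrow(x$grid2d),
              if (!is.null(x$grid1d)) sprintf(", %d 1D bin counts",
                                              nrow(x$grid1d)) else ""))
  best <- x$grid2d[which.max(x$grid2d$roc_auc_mean), ]
  cat(sprintf("  best 2D by ROC AUC: (%d, %d) AUC %.3f\n",
              best$n_mz, best$n_int, best$roc_auc_mean))
  invisible(x)
}

#' Heatmap-ready matrix of a grid-search metric
#'
#' @param result an `ms2_grid_search`.
#' @param metric one of `"accuracy"`, `"average_precision"`, `"roc_auc"`,
#'   `"log_loss"`.
#' @return Matrix with m/z bin counts on rows and intensity bin counts on
#'   columns, suitable for `image()` or `pheatmap`.
#' @export
grid_metric_matrix <- function(result, metric = "roc_auc") {
  stopifnot(inherits(result, "ms2_grid_search"))
  g <- result$grid2d
  col <- paste0(metric, "_mean")
  stopifnot(col %in% names(g))
  rows <- sort(unique(g$n_mz)); cols <- sort(unique(g$n_int))
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(mz = rows, intensity = cols))
  m[cbind(match(g$n_mz, rows), match(g$n_int, cols))] <- g[[col]]
  m
}
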