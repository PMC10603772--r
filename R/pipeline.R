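#' Pipeline configuration
#'
#' One object collecting every knob of the end-to-end workflow
#' (simulate/read -> preprocess -> featurize -> select -> train ->
#' threshold -> evaluate). Defaults are the method's stated settings: 5%
#' noise filter, 10 CV folds, beta = 0.5, test fraction 0.322, and the
#' standard hyperparameter grid available via `hp = "grid"`.
#'
#' @param input path to an MGF/MSP spectrum file, or `NULL` to simulate.
#' @param labels path to a label CSV (`id,label`), or `NULL`.
#' @param simulate list with `n` and `frac_good` for the synthetic
#'   generator, used when `input` is `NULL`.
#' @param noise_threshold relative-intensity noise cutoff.
#' @param family feature family, see [featurize()].
#' @param n_mz,n_int grid dimensions for the grid families.
#' @param correlation_filter apply the Spearman correlation filter
#'   (handcrafted/distance/combined families only).
#' @param cutoff dissimilarity cutoff for the correlation filter.
#' @param rfecv apply [rfecv_select()] after the correlation filter.
#' @param hp `"default"` (fixed hyperparameters), `"grid"` (tune over
#'   [ms2_hp_grid()]), or a data.frame of candidates.
#' @param cv_folds cross-validation folds.
#' @param beta F-beta parameter for threshold optimization.
#' @param test_fraction held-out fraction for final testing.
#' @param seed master seed; all randomness (generator, folds, forests) is
#'   fanned out deterministically from it.
#' @param out_dir directory for artifacts (`NULL` = no files written).
#' @return A list of class `ms2_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, labels = NULL,
                            simulate = list(n = 1399, frac_good = 0.44),
                            noise_threshold = 0.05,
                            family = "handcrafted", n_mz = 19,
                            n_int = if (identical(family, "grid1d")) 14 else 1,
                            correlation_filter = FALSE, cutoff = 0.3,
                            rfecv = FALSE, hp = "default", cv_folds = 10,
                            beta = 0.5, test_fraction = 0.322, seed = 1L,
                            out_dir = NULL) {
  cfg <- list(input = input, labels = labels, simulate = simulate,
              noise_threshold = noise_threshold, family = family,
              n_mz = n_mz, n_int = n_int,
              correlation_filter = correlation_filter, cutoff = cutoff,
              rfecv = rfecv, hp = hp, cv_folds = cv_folds, beta = beta,
              test_fraction = test_fraction, seed = as.integer(seed),
              out_dir = out_dir)
  stopifnot(cfg$noise_threshold >= 0, cfg$noise_threshold < 1,
            cfg$beta > 0, cfg$test_fraction > 0, cfg$test_fraction < 1,
            cfg$cv_folds >= 2)
  class(cfg) <- "ms2_pipeline_config"
  cfg
}

# 32-bit FNV-1a hash of a string; identifies the config in every artifact
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256  # xor only touches the low byte (b < 256)
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  # h < 2^32 may overflow R integers; format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null"))
}

resolve_hp_grid <- function(hp) {
  if (is.data.frame(hp)) return(hp)
  switch(hp, default = NULL, grid = ms2_hp_grid(),
         stop("hp must be 'default', 'grid' or a data.frame"))
}

load_or_simulate <- function(config) {
  if (!is.null(config$input)) {
    spectra <- read_spectra(config$input)
    if (!is.null(config$labels))
      spectra <- attach_labels(spectra, read_label_table(config$labels))
    spectra
  } else {
    generate_dataset(synthetic_config(n_spectra = config$simulate$n,
                                      frac_good = config$simulate$frac_good,
                                      seed = config$seed))
  }
}

#' Run the end-to-end training workflow
#'
#' Loads (or simulates) labeled spectra, preprocesses and featurizes them,
#' optionally applies the correlation filter and RFECV on the training
#' part, fits the spectrum-quality forest, tunes the decision threshold on
#' out-of-fold cross-validation predictions of the training set (so no test
#' information leaks into the threshold), and evaluates on the held-out
#' test set. Deterministic given `config$seed`. When `config$out_dir` is
#' set, writes `features.csv`, `model.rds`, and `evaluation.json` (the
#' latter embedding the config and its hash).
#'
#' @param config a [pipeline_config()].
#' @return List of class `ms2_run`: `model` ([ms2rf()] with tuned
#'   threshold), `cv` (training cross-validation), `eval` (test-set
#'   [evaluate()] report), `threshold`, `split` sizes, `features_used`,
#'   `config`, `config_hash`, and artifact `paths` (or `NULL`).
#' @export
run_train <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ms2_pipeline_config"))
  spectra <- load_or_simulate(config)
  if (anyNA(spectrum_labels(spectra)))
    stop("training requires fully labeled spectra")
  pre <- preprocess_spectra(spectra, config$noise_threshold)
  fset <- featurize_dataset(pre, config$family, n_mz = config$n_mz,
                            n_int = config$n_int)
  split <- split_train_test(fset, config$test_fraction, seed = config$seed + 1L)
  train <- split$train; test <- split$test

  keep <- colnames(train$features)
  if (config$correlation_filter &&
      config$family %in% c("handcrafted", "distance", "combined")) {
    D <- spearman_dissimilarity(train$features)
    keep <- correlation_filter(D, config$cutoff)
  }
  if (config$rfecv && length(keep) >= 2) {
    sel <- rfecv_select(train$features[, keep, drop = FALSE], train$labels,
                        k = config$cv_folds, seed = config$seed + 2L)
    keep <- sel$selected
  }
  xtr <- train$features[, keep, drop = FALSE]
  xte <- test$features[, keep, drop = FALSE]

  model <- ms2rf(xtr, train$labels, hp_grid = resolve_hp_grid(config$hp),
                 cv_folds = config$cv_folds, seed = config$seed + 3L)
  cv <- cross_validate(xtr, train$labels, k = config$cv_folds,
                       hp = as.data.frame(model$hyperparameters),
                       seed = config$seed + 4L)
  thr <- optimize_threshold(cv$oof_prob, cv$labels, beta = config$beta)
  model <- set_threshold(model, thr$threshold)
  ev <- evaluate(model, xte, test$labels)

  hash <- config_hash(config)
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(features = file.path(config$out_dir, "features.csv"),
                  model = file.path(config$out_dir, "model.rds"),
                  eval = file.path(config$out_dir, "evaluation.json"))
    write_features_csv(fset, paths$features)
    save_model(model, paths$model, config_hash = hash)
    cfg_out <- unclass(config)
    cfg_out$out_dir <- NULL  # path-independent report, like the hash
    report <- list(config_hash = hash, config = cfg_out,
                   split = list(train = nrow(xtr), test = nrow(xte)),
                   features_used = keep, threshold = thr$threshold,
                   cv_mean = as.list(cv$mean), cv_sd = as.list(cv$sd),
                   test = list(accuracy = ev$accuracy, precision = ev$precision,
                               recall = ev$recall,
                               average_precision = ev$average_precision,
                               roc_auc = ev$roc_auc, log_loss = ev$log_loss,
                               confusion = as.list(ev$confusion)))
    jsonlite::write_json(report, paths$eval, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  structure(list(model = model, cv = cv, eval = ev, threshold = thr$threshold,
                 split = c(train = nrow(xtr), test = nrow(xte)),
                 features_used = keep, config = config, config_hash = hash,
                 paths = paths),
            class = "ms2_run")
}

#' @export
print.ms2_run <- function(x, ...) {
  cat(sprintf("<ms2_run> family '%s', %d train / %d test, config %s\n",
              x$config$family, x$split["train"], x$split["test"], x$config_hash))
  cat(sprintf("  threshold %.3f (F-beta, beta = %g)\n", x$threshold, x$config$beta))
  print(x$eval)
  invisible(x)
}

#' Save or load a trained model bundle
#'
#' Single-file bundle (RDS) containing a schema version, the fitted forest,
#' scaler statistics, decision threshold, ordered feature names and the
#' originating config hash.
#'
#' @param model a fitted [ms2rf()].
#' @param path file path.
#' @param config_hash optional provenance hash embedded in the bundle.
#' @export
save_model <- function(model, path, config_hash = NA_character_) {
  stopifnot(inherits(model, "ms2rf"))
  saveRDS(list(schema_version = 1L, config_hash = config_hash, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$schema_version, 1L))
    stop("unsupported model bundle schema version: ", bundle$schema_version)
  bundle$model
}

#' Predict spectrum quality for (possibly unlabeled) spectra
#'
#' Preprocesses and featurizes spectra with the same settings the model was
#' trained under, and reports the probability of good diagnostic
#' information plus the label at the model's stored threshold. Spectra
#' emptied by the noise filter flow through as all-zero feature rows.
#'
#' @param model a fitted [ms2rf()] or a bundle path for [load_model()].
#' @param spectra list of raw [ms2_spectrum()] objects, or an MGF/MSP path.
#' @param config a [pipeline_config()] carrying the preprocessing and
#'   featurization settings (family and grid dimensions must match
#'   training).
#' @param out optional CSV path for the predictions.
#' @return data.frame with columns `id`, `probability_good`, `label`.
#' @export
run_predict <- function(model, spectra, config = pipeline_config(), out = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(spectra)) spectra <- read_spectra(spectra)
  pre <- preprocess_spectra(spectra, config$noise_threshold)
  fset <- featurize_dataset(pre, config$family, n_mz = config$n_mz,
                            n_int = config$n_int)
  x <- fset$features[, model$feature_names, drop = FALSE]
  if (!identical(colnames(x), model$feature_names))
    stop("featurization does not produce the model's feature set; ",
         "check family/grid settings")
  p <- predict(model, x, type = "prob")
  res <- data.frame(id = fset$ids, probability_good = unname(p),
                    label = ifelse(p >= model$threshold, "good", "poor"))
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
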