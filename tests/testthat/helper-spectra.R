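# Fixture builders and independent naive oracles used across the suite.
# Oracles deliberately avoid the package's code paths: statistics are
# computed from first principles and binning by explicit edge comparison.

random_raw_spectrum <- function(id = "r", n = 20, precursor = 400) {
  ms2_spectrum(id, precursor, sample(c(10, 20, 35, 50, 65, 80, 100), 1),
               mz = runif(n, 50, precursor * 1.05),
               intensity = rlnorm(n, meanlog = 6, sdlog = 2))
}

random_norm_spectrum <- function(id = "r", n = 20, precursor = 400) {
  denoise_spectrum(normalize_spectrum(random_raw_spectrum(id, n, precursor)))
}

# sample sd / quantile (type 7) from first principles
naive_sd <- function(x) {
  if (length(x) < 2) return(0)
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
naive_quantile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- min(lo + 1, n)
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}
naive_entropy <- function(v) {
  tot <- sum(v)
  if (!length(v) || tot == 0) return(0)
  e <- 0
  for (x in v) if (x > 0) e <- e - (x / tot) * log(x / tot)
  e
}

naive_distance_stats <- function(spec) {
  pk <- spec$peaks
  n <- nrow(pk)
  if (!n) return(rep(0, 8))
  mc <- sum(pk[, 1] * pk[, 2]) / sum(pk[, 2])
  ic <- sum(pk[, 2]) / n
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt((pk[i, 1] - mc)^2 + (pk[i, 2] - ic)^2)
  unname(c(n, sum(d) / n, naive_sd(d), min(d), max(d),
           naive_quantile(d, 0.25), naive_quantile(d, 0.5),
           naive_quantile(d, 0.75)))
}

naive_balance <- function(spec, n_bins = 10) {
  pk <- spec$peaks
  if (!nrow(pk)) return(0)
  w <- max(pk[, 1]) / n_bins
  first <- 0; rest <- 0
  for (i in seq_len(nrow(pk))) {
    if (pk[i, 1] < w) first <- first + pk[i, 2]
    else rest <- rest + pk[i, 2]
  }
  unname(rest - first)
}

naive_handcrafted <- function(spec, balance_bins = 10) {
  pk <- spec$peaks
  n <- nrow(pk)
  if (!n) return(rep(0, 12))
  mz <- pk[, 1]; int <- pk[, 2]
  raw <- mz * spec$precursor_mz
  n_win <- max(1, ceiling((max(raw) - min(raw)) / 2))
  unname(c(n, sum(int) / n, sum(int), naive_sd(int), sum(mz * int),
           sum(int > 0.1), sum(int > 0.2),
           if (n > 2) naive_sd(diff(sort(mz))) else 0,
           n / n_win, naive_balance(spec, balance_bins),
           naive_entropy(mz), naive_entropy(int)))
}

naive_grid2d <- function(spec, n_mz, n_int, int_min = 0.05) {
  counts <- matrix(0, n_mz, n_int)
  mz_edges <- seq(0, 1, length.out = n_mz + 1)
  int_edges <- seq(int_min, 1, length.out = n_int + 1)
  pk <- spec$peaks
  for (p in seq_len(nrow(pk))) {
    i <- findInterval(pk[p, 1], mz_edges, rightmost.closed = FALSE)
    i <- min(max(i, 1), n_mz)                       # [e_{k-1}, e_k), clamp overflow
    j <- n_int
    for (b in seq_len(n_int))                       # (e_{j-1}, e_j]
      if (pk[p, 2] <= int_edges[b + 1]) { j <- b; break }
    counts[i, j] <- counts[i, j] + 1
  }
  as.numeric(t(counts))
}

naive_grid1d <- function(spec, n_int, int_min = 0.05) {
  counts <- numeric(n_int)
  edges <- int_min * (1 / int_min)^(seq(0, n_int) / n_int)
  pk <- spec$peaks
  for (p in seq_len(nrow(pk))) {
    j <- n_int
    for (b in seq_len(n_int)) if (pk[p, 2] <= edges[b + 1]) { j <- b; break }
    counts[j] <- counts[j] + 1
  }
  counts
}

# exhaustive F-beta threshold search over a dense cutoff set
naive_best_threshold <- function(prob, labels, beta) {
  y <- labels == "good"
  cand <- sort(unique(c(0, prob, 1)))
  best_f <- -1; best_t <- NA
  for (t in cand) {
    pred <- prob >= t
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    prec <- if (tp + fp) tp / (tp + fp) else NA
    rec <- if (tp + fn) tp / (tp + fn) else NA
    f <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0 ||
             (beta^2 * prec + rec) == 0) 0
         else (1 + beta^2) * prec * rec / (beta^2 * prec + rec)
    if (f >= best_f - 1e-12) { best_t <- t; best_f <- max(best_f, f) }
  }
  list(threshold = best_t, f_beta = best_f)
}

small_hp <- function(trees = 100)
  data.frame(n_estimators = as.integer(trees), max_depth = NA_integer_,
             min_samples_split = 2L, min_samples_leaf = 1L)
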