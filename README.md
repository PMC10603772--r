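# ms2quality

Automatic assessment of the diagnostic information content of tandem mass
(MS2) spectra of small, environmentally relevant molecules.

Suspect and non-target screening by LC-HRMS depends on MS2 spectra that
actually say something about the structure of the precursor ion: several
intense fragment ions, spread over the m/z range below the precursor, not
drowned in noise and not dominated by the unfragmented precursor itself.
Many acquired spectra fail these expectations, and downstream steps —
library matching, molecular networking, structure and toxicity prediction —
silently degrade when fed such spectra. `ms2quality` trains a random-forest
classifier to separate spectra providing *good* diagnostic information from
*poor* ones, so that spectrum triage can be automated in post-processing or,
eventually, at acquisition time.

## Method in brief

Each centroided spectrum (peak list with precursor m/z and collision
energy) is preprocessed: intensities are divided by the base-peak intensity,
m/z values by the precursor m/z, and peaks with relative intensity ≤ 5% of
the base peak are removed as noise. Three feature families summarize the
result:

- **Distance features** (10): the spectrum centroid is
  c = (Σmᵢiᵢ/Σiᵢ, Σiᵢ/n) in normalized (m/z, intensity) space; the
  per-peak Euclidean distances dₚ = √((mₚ−m_c)² + (iₚ−i_c)²) are summarized
  by count, mean, SD, min, max and quartiles.
- **Handcrafted features** (14): peak count, intensity moments, the
  m/z·intensity dot product, counts above 0.1/0.2 relative intensity,
  consecutive-m/z-gap SD, fragments per 2 Da, intensity balance, and
  Shannon entropies of the m/z and intensity vectors.
- **Grid features**: peak counts on a 1D geometric intensity grid or a 2D
  m/z × intensity lattice (1–20 bins per axis; the (1,1) grid degenerates
  to the peak count, which also serves as a single-feature baseline).

Precursor m/z and collision energy terminate every feature vector. A random
forest (balanced class weights, √p feature subsampling, optional exhaustive
search over a 108-point hyperparameter grid) is validated by stratified
10-fold cross-validation (accuracy, average precision, ROC AUC, log loss).
Feature sets can be refined by Spearman-dissimilarity clustering
(D = 1 − |ρ|, cut at 0.3) and recursive feature elimination with
cross-validation. Finally the decision threshold is tuned by maximizing
F₀.₅ = 1.25·P·R/(0.25·P + R), which weights precision twice as heavily as
recall — mislabeling a poor spectrum as good costs more than the reverse.

A synthetic spectrum generator emulates the intended data regime (~1400
spectra, 44% good, precursors 100–900 Da, HCD collision energies 10–100%)
by constructing good spectra that satisfy five quantified quality criteria
and poor spectra that violate a randomly chosen one; a rule-based labeler
scores any spectrum against the same criteria.

## Worked example

```r
library(ms2quality)

spectra <- generate_dataset(synthetic_config(n_spectra = 400, seed = 42))
pre     <- preprocess_spectra(spectra)          # normalize + 5% noise filter
fs      <- featurize_dataset(pre, "handcrafted")
split   <- split_train_test(fs, test_fraction = 0.322, seed = 42)

fit <- ms2rf(split$train, seed = 42)
cv  <- cross_validate(split$train, k = 10, seed = 42)
cv
#> <ms2_cv> 10-fold stratified cross-validation, n = 271
#>      accuracy average_precision roc_auc log_loss
#> mean   0.9265            0.9795  0.9786   0.1837
#> sd     0.0453            0.0194  0.0230   0.0813

thr <- optimize_threshold(cv$oof_prob, cv$labels, beta = 0.5)
fit <- set_threshold(fit, thr$threshold)
evaluate(fit, split$test)
#> <ms2_eval> n = 129, threshold = 0.642
#>   accuracy 0.915  precision 1.000  recall 0.807
#>   average precision 0.985  ROC AUC 0.986  log loss 0.182
#>   confusion: TP 46  FP 0  TN 72  FN 11
```

The cross-validation summary shows the forest's validation metrics on the
271 training spectra (mean ± SD over 10 folds). The F₀.₅-optimized
threshold (0.642, chosen on out-of-fold predictions only) trades recall for
precision on the 129 held-out spectra: every spectrum called *good* really
is good (precision 1.00), at the cost of missing 11 genuinely good ones.
`feature_importance(fit)` shows the m/z·intensity dot product, the
consecutive-m/z-gap SD and the intensity sum as the strongest predictors.

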