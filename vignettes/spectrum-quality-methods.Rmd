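---
title: "Classifying the diagnostic quality of MS2 spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the diagnostic quality of MS2 spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ms2quality)
```

## The problem and the model

An MS2 spectrum is diagnostically useful when it contains several intense
fragment ions, spread across the m/z range below the precursor, clearly
separated from noise, and not dominated by the surviving precursor ion.
`ms2quality` treats "good vs poor diagnostic information" as a binary
classification problem over engineered peak-list descriptors, solved with a
random forest. The forest is a natural fit: the relationships between peak
statistics and perceived quality are nonlinear and interacting, sample
sizes are modest (~10³ spectra), and impurity-based importances keep the
model interpretable.

The classifier never sees the raw peak list. Every spectrum is first
mapped to dimensionless coordinates — intensities relative to the base
peak, m/z relative to the precursor — so that spectra of molecules with
very different masses and ionization efficiencies become comparable, and
peaks at relative intensity ≤ 5% are discarded as noise. All features are
functions of this normalized, denoised representation (two exceptions are
deliberate: the fragments-per-2-Da density is computed on de-normalized
m/z, because a Dalton has no meaning after normalization, and the two
global descriptors — precursor m/z in Da and collision energy in % — are
appended untransformed to every feature vector).

### Assumptions

- Spectra are centroided; profile data are out of scope.
- Precursor m/z and collision energy are known for every spectrum (they
  are required metadata, not optional annotations).
- The quality notion is binary. No attempt is made to produce a calibrated
  continuous quality score.
- "good" is the positive class for precision, recall, and average
  precision everywhere.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| noise threshold | 0.05 | relative intensity | peaks at ≤ 5% of the base peak are treated as noise; the boundary value itself is dropped (strict `>` keeps) |
| grid dimensions | 2D (19, 1); 1D 14 | bins | best-performing grids in the package's own sweeps at desk scale; both exposed, sweep with `grid_bin_search()` |
| intensity-balance bins | 10 | bins | literature leaves the count open; 10 gives a stable signed low-m/z/high-m/z contrast; exposed as `balance_bins` |
| dissimilarity cutoff | 0.3 | D = 1 − \|ρ\| | features closer than 0.3 are treated as redundant duplicates |
| CV folds | 10 | — | stratified; on 949 training spectra the modal fold fits on 854 and predicts on 95 |
| test fraction | 0.322 | — | yields a 949/450 split on 1399 spectra with class balance preserved |
| F-beta | β = 0.5 | — | weights precision twice as heavily as recall: a poor spectrum mislabeled good is the costly error |
| hyperparameter grid | 108 points | — | trees {50,100,200} × depth {∞,10,20,30} × min split {2,5,10} × min leaf {1,2,4}; `hp = "grid"` tunes over it, the default is the fixed corner (200, ∞, 2, 1) |

The forest always uses bootstrap resampling, balanced class weights
(n/(2·n_class)), √p feature subsampling and a fixed seed; with one thread
the whole pipeline is bit-reproducible.

## The synthetic data generator

Real labeled spectra require an instrument and an expert. The generator
(`generate_dataset()`) instead emulates the intended data regime so the
pipeline can be exercised and validated at desk scale: 1399 spectra per
dataset, 44% good, precursor m/z uniform in 100–900 Da, collision energy
drawn from {10, 20, 35, 50, 65, 80, 100}%, raw intensities spanning
10⁴–10⁷ counts.

Good spectra are built to satisfy five quantified quality criteria: (i) at
least two (actually 3–12) diagnostic fragments (ii) above 5% relative
intensity, (iii) spread over the m/z range (the generator anchors one
fragment near the low end and one near the precursor), (iv) any precursor
peak kept below the 25th percentile of the fragment intensities, and (v)
only light sub-5% noise. Poor spectra violate exactly one randomly chosen
criterion — a lone dominant fragment, a tight fragment cluster, a
precursor-dominated spectrum, or a spectrum buried in sub-threshold noise —
recorded in the spectrum metadata. The rule-based labeler
(`rule_label()`) scores any spectrum against the same quantified criteria;
on default-configuration data it recovers the generated class on ≥ 99% of
spectra, which is verified in the test suite.

Two of the five criteria have no quantitative definition in expert
practice; the package's operational choices are: fragment span ≥ 0.5 of
the range from the lowest retained fragment up to the precursor (iii), and
at most 80% of pre-filter peaks below the noise floor (v). Both are
exposed in `quality_thresholds()` so a different labeling policy can be
dialed in.

What the generator does **not** emulate: fragmentation chemistry (no
distinction between diagnostic losses and nonspecific ones such as water
loss), isotope patterns, mass-accuracy errors, detector noise structure,
or correlations between collision energy and fragmentation degree.
Consequently, passing tests demonstrate that the pipeline's machinery is
correct and that the features carry the intended signal — not that the
headline numbers transfer to instrument data. On synthetic data the
classes are close to separable (held-out accuracy is typically above 0.9,
ROC AUC above 0.95), which is more benign than manually labeled real
spectra. One visible consequence: the single-feature peak-count baseline
is comparatively strong here: feature families beat it on held-out ROC
AUC, but the 1D-grid margin is small (around one or two percentage points)
and can vanish on unlucky seeds.

## Numerical choices

- **Centroid definition.** The centroid's m/z coordinate is
  intensity-weighted (Σmᵢiᵢ/Σiᵢ); its intensity coordinate is the plain
  mean (Σiᵢ/n). The definition is isolated in `compute_centroid()` so an
  alternative reading (e.g. both coordinates weighted) is a one-line swap.
- **Binning conventions.** 2D grids: m/z bins are equal-width over [0, 1],
  left-closed, with peaks above the precursor (m/z > 1, isotopes/adducts)
  clamped into the top bin; intensity bins are equal-width over (0.05, 1],
  right-closed. 1D grids place bin edges geometrically,
  0.05·20^(k/n), so low intensities get narrower bins. Flattening is
  m/z-major, so with one intensity bin cell C0 is the lowest-m/z column.
- **Degenerate inputs.** A spectrum emptied of peaks yields an all-zero
  descriptor row (count 0) in every family rather than an error, so
  prediction never crashes. A single peak is its own centroid: distance
  statistics are 0 with count 1. Standard deviations of fewer than two
  values are defined as 0. Entropy uses 0·ln 0 = 0; all-zero input gives 0.
- **Quartiles and SD.** Quartiles use R's default (type 7) linear
  interpolation; spreads are sample standard deviations (n − 1).
- **Threshold search.** F_β is evaluated at every distinct predicted
  probability plus the boundary cutoffs {0, 1}; the decision rule is
  `prob ≥ threshold`, and ties are broken toward the higher threshold
  (toward precision). The threshold is tuned on out-of-fold CV predictions
  of the training set, never on test data.
- **Correlation filter.** Average-linkage hierarchical clustering on
  D = 1 − |ρ|, tree cut at the cutoff; the retained representative of each
  cluster is the member with the highest mean dissimilarity to features
  outside the cluster (most non-redundant), ties broken lexicographically.
  Constant columns get ρ := 0 (D = 1) with a warning. Grid families are
  excluded from correlation testing: their cell counts are structurally
  sparse and rank correlations between them are not meaningful the way
  they are between heuristic descriptors.
- **RFECV.** Step size 1, scored by cross-validated average precision
  (precision-first, consistent with the β = 0.5 deployment criterion), and
  the returned subset is the smallest within one standard error of the
  best — a deliberate parsimony bias.
- **Baseline.** The peak-count baseline carries exactly one feature; the
  two global descriptors are *not* appended, otherwise it would not be a
  peak-count baseline.
- **Class counts.** `generate_dataset()` produces exactly
  `floor(frac_good · n)` good spectra (1399 × 0.44 → 615); the stratified
  split allocates `round(test_fraction · n)` test spectra across classes by
  largest remainder, so 1399 → 949/450 with both sides at 44% good.

## Problem sizes

The test suite validates feature oracles on 200 random spectra, labeler
agreement on 1000 generated spectra, and the full pipeline plus the
family-vs-baseline comparison on one 1399-spectrum dataset; RFECV recovery
uses 20 runs at n = 120 with 5 folds. `scripts/acceptance.R` repeats the
1399-spectrum study end to end, tuning over the 8 corner points of the
hyperparameter grid — enough to exercise the tuner while keeping a full
run around ten seconds; the complete 108-point grid is available with
`hp = "grid"` and is itself shape-tested.

## Known limitations

- Trained and validated on synthetic spectra unless the user supplies
  labeled MGF/MSP data; transfer to a particular instrument/ionization
  setup needs its own labeled set.
- The five quality criteria are operational quantifications of expert
  judgment; criterion (i)'s "diagnostic" fragment is approximated by "any
  sufficiently intense, well-spread, non-precursor fragment" because a bare
  peak list carries no structural information.
- MGF/MSP dialect support is deliberately narrow (PEPMASS/PrecursorMZ,
  COLLISION_ENERGY/CollisionEnergy); mzML and profile data are out of
  scope.
- Probabilities are not calibrated; the F₀.₅ threshold corrects the
  operating point, not the probability scale.
```{r session}
sessionInfo()
```
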