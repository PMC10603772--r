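Package: ms2quality
Title: Diagnostic-Quality Classification of Tandem Mass Spectra of Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated assessment of the diagnostic information content of
    centroided tandem mass (MS2) spectra of small, environmentally relevant
    molecules. Spectra are normalized to the base peak and precursor m/z,
    noise-filtered, and summarized by three engineered feature families
    (centroid-distance statistics, handcrafted peak descriptors, and 1D/2D
    grid-binned counts). A random forest classifier with balanced class
    weights distinguishes spectra providing good from poor diagnostic
    information; decision thresholds are tuned with the F-beta score to
    favor precision. Includes Spearman-dissimilarity correlation filtering,
    recursive feature elimination with cross-validation, a grid-bin
    hyperparameter search, MGF/MSP readers and writers, and a synthetic
    labeled-spectrum generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ranger,
    pROC,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
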