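Package: metaboflow
Title: Optimized Untargeted LC-HRMS Metabolomics: ROI Trimming, DoE
    Peak-Picking Optimization, Adaptive Batch Correction and
    Empirical-Compound Pathway Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for global (untargeted) LC-HRMS
    metabolomics. Raw centroided runs are trimmed to regions of interest
    enriched for genuine chromatographic peaks; centWave-style peak
    detection parameters are then optimized by a Box-Behnken
    design-of-experiments search maximizing a composite Quality Score
    built from isotope-supported reliable peaks, Gaussian peak-shape
    ratio and peak-group stability. Batch effects in feature tables are
    corrected by ComBat, EigenMS-style SVD bias removal or QC-based
    robust LOESS signal correction, with automatic selection of the
    best-performing method by ordination-based inter-batch distances.
    Pathway activity is predicted directly from m/z features via
    retention-time-aware empirical-compound construction and
    permutation-calibrated enrichment (mummichog v2 scheme). A synthetic
    data module generates ground-truthed runs, dilution series, batched
    tables and pathway libraries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    mzR,
    sva,
    vegan,
    minpack.lm,
    fitdistrplus,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
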