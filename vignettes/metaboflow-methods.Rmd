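---
title: "Methods: ROI trimming, DoE peak-picking optimization, batch correction selection, and empirical-compound pathway activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models and procedures implemented in
`metaboflow`, their assumptions, the tunable parameters, and the design
choices made where the design was genuinely open. The package addresses
four stages of an untargeted LC-HRMS metabolomics workflow: trimming raw
runs to regions of interest (ROIs), optimizing peak-picking parameters by
a Box-Behnken design of experiments (DoE), selecting a batch-effect
correction automatically, and predicting pathway activity directly from
m/z features through retention-time-aware empirical compounds.

## Region-of-interest trimming

Recursive peak detection over complete spectra is what makes parameter
optimization slow. `selectROIs()` instead divides the m/z range into
`nBins` equal bins (default 4), slides a window of `mzWindowFraction`
(default 0.25) of each bin's width across the bin, and keeps the position
with the highest summed centroid intensity. One shared window of
`rtFraction` (default 0.25) of the retention-time span slides across the
whole RT axis the same way. Each bin's best m/z window intersected with
the single best RT window is one ROI; `trimRun()` assembles the trimmed
run from the centroids inside their union. Because LC-HRMS spectra are
sparse, windows that maximize summed intensity still carry plenty of
low-intensity signal, so optimization on the trimmed run is not biased
toward tall peaks only (this enrichment property is tested against the
planted ground truth).

Numerical choices: the sliding step is window width / 10, fine enough to
locate the maxima at the scales involved; ties break toward lower m/z /
earlier RT so the search is deterministic; the "scan intensity sum" is
the sum of centroid intensities inside the window, not whole-scan TIC;
one global RT window is used rather than one per bin.

## Peak detection and the Quality Score

`pickPeaks()` is a centWave-style detector: pooled centroids are chained
into m/z traces within a `ppm` tolerance; traces must show at least
`prefilterK` consecutive scans above `prefilterI` counts and an apex
above `noise`; apexes are located on a Gaussian-smoothed EIC and bounds
delimited at flanking valleys or baseline; peaks must have a base width
inside `[peakwidthMin, peakwidthMax]` seconds and a signal-to-noise ratio
of at least `snthresh`; peaks closer than `mzdiff` Th with overlapping RT
ranges merge. Each peak's EIC is fitted with a Gaussian
(`h exp(-(t-mu)^2 / (2 sigma^2))`, Levenberg-Marquardt); the shape score
is the Pearson correlation between fitted and observed intensities with
its two-sided correlation-test p-value, and a peak is called *Gaussian*
when `cor >= 0.9` and `p <= 0.05` (both thresholds non-strict).

`groupAndAlign()` groups peaks across samples by kernel density over RT
(bandwidth `bw`) within m/z slices, aligns samples by LOESS on the
residuals of well-behaved groups (at least `minfrac` of samples, exactly
one peak each; spanning more than one sample), and summarizes alignment
and grouping quality as `RCS = 1 / (1 + mean |post-alignment residual|)`
and `GS = good^2 / (bad + 1)`. These concrete forms are this package's
choice: both enter the score only after min-max normalization, so only
their orderings matter, and both are monotone in the quality they
measure.

`detectIsotopes()` flags a feature as a *reliable peak* (RP) when another
feature sits at `+1.003355/z` (z = 1 or 2) within tolerance, co-elutes
within 3 s, and has an intensity ratio in (0, 0.6] — deliberately loose
bounds favoring recall, since RP inflation is penalized elsewhere. A
reliable peak is a *low-intensity-isotope peak* (LIP) when its isotope's
mean intensity falls below the mean of the lowest 3% of feature
intensities.

The DoE response variable is the Quality Score

```
QS = RP^1.5 / (allPeaks - LIP) * GR^2 * QcoE
```

with `GR` the Gaussian peak ratio and `QcoE` the quality coefficient,
the weighted combination `0.4 normRCS + 0.4 normGS + 0.2 norm(1 - CV)`
rescaled to [0, 1]. Guards and choices the bare formula leaves open:

* `QS = 0` when `allPeaks = 0` or `allPeaks <= LIP` (the raw denominator
  would be zero or negative).
* CV (the median per-feature coefficient of variation across replicate
  injections) enters inverted, `1 - normCV`: low variation is good, and
  rewarding high CV would reward noise.
* "Unit-based" normalization is min-max over the current design round's
  evaluations; the round is the natural cohort. A degenerate cohort
  (max = min) contributes a neutral 0.5. Outside a round (comparing two
  arbitrary parameter sets), every component is held at the neutral 0.5
  so that scores are cohort-independent; `evaluatePickerParams()` reports
  this neutral score.

## DoE optimization

`optimizeParams()` first fixes `noise`, `prefilter` and `ppm` from the
data: the noise floor is the antimode of a kernel density estimate of
log10 intensities separating the dominant noise mode from the signal
mode (falling back to 3x the median intensity when the density is
unimodal, with a warning); `prefilterK` is the modal consecutive-scan
length of above-floor traces, clamped to [2, 10]; `ppm` is the 95th
percentile of within-trace deviations from the intensity-weighted trace
mean.

The five remaining factors (`peakwidthMin`, `peakwidthMax`, `mzdiff`,
`snthresh`, `bw`) are searched with a standard 5-factor Box-Behnken
design: the four (+/-1, +/-1) combinations for each of the 10 factor
pairs (40 edge runs) plus 6 center replicates. Rows whose decoded
`peakwidthMin >= peakwidthMax` are repaired by swapping (equal widths
additionally shrink the minimum by 20%) and recorded. A full quadratic
response surface is fitted to the round's QS values and its optimum over
the coded cube `[-1, 1]^5` found by box-constrained quasi-Newton
refinement from the cube corners, the center and the best observed
point; factors pinned at |coded| > 0.95 have their range shifted and
expanded by 50% for the next round. The loop converges when the round's
best score improves by less than `relTol` (default 5%) or after
`maxRounds` (default 6).

Two conventions matter for reproducibility. The returned parameters are
the best *evaluated* point, never the surface prediction (robust to a
poor quadratic fit). And the initial parameter set is itself evaluated
as the incumbent, so optimization can never return parameters worse than
the starting point under the neutral score — the score used for all
cross-round and cross-parameter comparisons, because round-normalized
scores are not comparable between cohorts.

## Batch-effect correction and automatic selection

Three correctors cover the main assumption classes:

* `correctCombat()` — empirical-Bayes location/scale adjustment on the
  log scale via `sva::ComBat`, preserving biological group effects.
* `correctEigenms()` — log-transform, remove per-feature group means,
  SVD of the residuals, permutation test on the leading singular values
  (within-row permutations, alpha = 0.05, 99 permutations, seeded),
  subtract the significant bias trends, restore group effects.
* `correctQcrlsc()` — per feature, LOESS of pooled-QC intensities
  against injection order (span 0.75, degree 1); all samples are divided
  by the fitted trend relative to the median QC level, with constant
  extrapolation beyond the first/last QC. Features with fewer than 3
  finite QC values are left uncorrected and counted.

Intensities are kept positive throughout; zeros are imputed to half the
feature minimum before any log transform; logs are natural.

`evaluateCorrection()` scores a table by ordination. The ordination is
chosen by the gradient length of the first detrended-correspondence-
analysis axis (`vegan::decorana`, detrending by 26 segments with Hill's
rescaling so the length is in SD units): PCA of the standardized log
matrix when the gradient exceeds 3, CCA constrained on batch otherwise.
The score has two terms, both lower-is-better:

1. **Chance-corrected batch separation.** The mean pairwise
   batch-centroid distance divided by the mean within-batch dispersion
   in the first two ordination axes, minus the 95th percentile of the
   same index under 49 random batch relabellings — with the CCA *refit
   per relabelling*, because a constrained ordination overfits whatever
   labels it is given — floored at zero. On data with no batch effect
   this term is ~0 for every candidate, so a corrector gains nothing by
   scrubbing chance structure.
2. **QC dispersion ratio.** The mean QC-to-QC-centroid distance divided
   by the mean biological-sample-to-centroid distance. The ratio is
   scale-free (ordination rescaling cancels) and rises toward 1 when
   uncorrected structured variance (drift, batch) inflates both
   dispersions jointly, since pooled QCs carry less biological variance
   than real samples.

`selectBestCorrection()` runs every feasible candidate, skips and logs
infeasible ones, and returns the minimum score — with a parsimony guard:
a corrector must beat the uncorrected score by more than 10% relative
*and* 0.1 absolute to displace "none". The absolute floor is set at the
magnitude of between-candidate score noise observed on null data at
typical QC counts, so that no-effect data keeps its identity transform
while genuine batch effects (whose improvements are an order of
magnitude larger) always clear it. Ties among improving correctors
resolve by the fixed precedence eigenms, combat, qc_rlsc.

## Empirical-compound pathway activity

`matchMz()` annotates each feature against every (compound, ion form)
pair within the instrument `ppm`; the ion-form table covers the common
positive and negative adducts, dimers and the doubly charged forms, and
the *primary ions* are M+H, M+Na and M-H2O+H (positive) and M-H, M-2H
and M-H2O-H (negative). Ion names tolerate whitespace, Unicode minus
signs and bare-sign charge brackets; all variants normalize to one
canonical spelling.

`buildEmpiricalCompounds()` runs three stages. (1) Per compound, matched
features are split by single-linkage clustering on RT with the window as
the threshold — the most permissive reading of "within an expected
retention-time window", appropriate because an empirical compound may be
an unresolved isomer mixture. The window is `rtTol` if given, otherwise
`max(RT) * rtFrac` with `rtFrac = 0.02`. (2) ECs are merged when they
share a member with the same ion form, the same m/z within `ppm`
(a strict-equality reading would never fire on floats) and RT within the
window. (3) When `forcePrimaryIon` (default), only ECs containing at
least one primary ion survive. All three stages are returned for
inspection, and containment `|final| <= |merged| <= |initial|` is an
invariant.

`enrichMummichog()` maps significant features (p <= `pCutoff`) to
significant ECs (any-member rule by default; a primary-member-only rule
is available), converts the pathway library to EC space, and tests each
pathway with a one-sided Fisher exact test with EASE correction (one hit
subtracted). The null model draws `nPerm` (default 100) feature lists of
the observed significant size from all features and recomputes the
per-pathway scores. The Gamma adjustment is fitted **per pathway** to
that pathway's own permutation null of `-ln p`, as a zero-inflated
Gamma: permutations yielding p = 1 form an atom at zero, the Gamma is
fitted by maximum likelihood to the positive part, and the reported
upper-tail probability is weighted by the positive fraction; an observed
score of zero (no hits) reports p = 1. A pooled fit across pathways was
rejected after calibration runs showed that the null's shape — not just
its scale — depends on the pathway's EC count, which compresses the
adjusted p-values of large pathways; the per-pathway zero-inflated fit
is uniform on null data (Kolmogorov-Smirnov p = 0.63 over 100 null
replicates in the package's calibration suite, with the 200-replicate
check in the test suite).

## The synthetic-data generators

Every generator is a pure function of its arguments and a seed and emits
its ground truth alongside the data.

* `simulateRun()` plants Gaussian-in-time peaks (closed form
  `h exp(-(t - apex)^2 / (2 sigma^2))`) on a regular scan grid with
  per-scan m/z jitter, optional isotope partners at `+1.003355/z` with
  relative abundance 0.05-0.3, and uniform-in-m/z noise points — matching
  the sparsity that makes ROI selection informative. It does **not**
  model chromatographic tailing, matrix effects or mass-calibration
  drift, so shape-sensitive results transfer to real data only insofar
  as real peaks are near-Gaussian.
* `simulateBatchedTable()` draws log-normal feature intensities, applies
  *feature-specific* batch multipliers (log-normal spread 0.15 around
  each batch's factor) and feature-specific injection-order drift
  (slopes jittered by U(0.5, 1.5)), and inserts pooled QCs (the mean
  biological profile plus reduced noise) every `qcEvery` injections.
  Feature-specific effects are deliberate: a uniform sample-wide
  multiplier is invisible to correspondence-analysis ordination (row
  standardization) and does not represent how LC-MS response drifts.
* `simulatePathwayData()` defaults to 120 compounds over 15 pathways —
  a scaled-down image of real pathway libraries; much smaller toys make
  the hypergeometric null too discrete for any calibration statement.
  Each compound emits 1-4 ion forms (primary present with probability
  0.9) co-eluting within a narrow RT window.

Problem sizes used in the validation suite — two 240 s runs of 24 peaks
per optimization dataset, ten datasets; 60-sample two-batch tables with
a QC every 8 injections; 200 replicates of the null enrichment — were
chosen so the whole suite runs on a single CPU in well under half an
hour while keeping every comparison statistically meaningful.

## Known limitations

* The picker is a from-scratch centWave-style detector validated by
  planted-truth recovery; it is not output-identical to any other
  implementation, and deconvolution of co-eluting isomers at identical
  m/z is out of scope.
* Only three correction methods ship; the selector accepts additional
  candidates through the same interface but does not implement them.
* Compound-space (retention-time-free) pathway analysis is intentionally
  unsupported; feature lists without RT raise an error.
* The EigenMS permutation test controls trend count at alpha = 0.05 per
  singular value; occasional removal of one noise trend on clean data is
  expected and harmless (the identity-preserving group means are
  restored).
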