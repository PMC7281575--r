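# The Quality Score: the DoE response variable. QS combines the count of
# isotope-supported reliable peaks (RP, exponent 1.5), the Gaussian
# peak-shape ratio (GR, exponent 2) and the quality coefficient QcoE, a
# 0.4/0.4/0.2-weighted combination of normalized alignment score (RCS),
# grouping score (GS) and inverted coefficient of variation.

#' Weighted QcoE combination
#'
#' The inner weighted sum of the quality coefficient: normalized
#' retention-time correction score, normalized grouping score and the
#' normalized inverted coefficient of variation, weighted 0.4, 0.4 and
#' 0.2 respectively. Exposed so the weights are directly measurable.
#'
#' @param normRcs,normGs,normCvInv components in [0, 1].
#' @return the weighted combination (in [0, 1] for unit-range inputs).
#' @export
qcoeCombine <- function(normRcs, normGs, normCvInv) {
  0.4 * normRcs + 0.4 * normGs + 0.2 * normCvInv
}

#' Quality Score closed form
#'
#' `QS = RP^1.5 / (allPeaks - LIP) * GR^2 * QcoE`, guarded to 0 when no
#' peaks were found or when the low-intensity-isotope count reaches the
#' total (the unguarded formula would divide by zero or flip sign).
#'
#' @param rp reliable peaks (features with a detectable isotope).
#' @param lip low-intensity-isotope peaks.
#' @param allPeaks total detected features.
#' @param gr Gaussian peak ratio in [0, 1].
#' @param qcoe quality coefficient in [0, 1].
#' @return the score (>= 0).
#' @export
qualityScore <- function(rp, lip, allPeaks, gr, qcoe) {
  if (allPeaks <= 0 || allPeaks <= lip) return(0)
  rp^1.5 / (allPeaks - lip) * gr^2 * qcoe
}

unitNorm <- function(x, lohi) {
  if (is.null(lohi) || !all(is.finite(lohi)) || diff(lohi) <= 0) return(0.5)
  min(max((x - lohi[1]) / (lohi[2] - lohi[1]), 0), 1)
}

#' Compute the Quality Score of a grouped feature set
#'
#' Counts reliable peaks (`hasIsotope`), low-intensity-isotope peaks, the
#' Gaussian ratio (`gaussCor >= 0.9` and `gaussP <= 0.05`), and the
#' median per-feature coefficient of variation within replicate groups;
#' normalizes RCS, GS and (1 - CV) over the supplied context (the min/max
#' of the raw values across the current design round) and combines them
#' with [qcoeCombine()]. A degenerate context (max = min) contributes a
#' neutral 0.5 for that component. When `normContext$qcoe` is present the
#' combined coefficient is further min-max rescaled over the round.
#'
#' @param fs a [FeatureSet-class] (isotope flags filled by
#'   [detectIsotopes()]).
#' @param replicateGroups list of sample-index vectors treated as
#'   replicate groups for the CV term (default: all samples as one
#'   group).
#' @param normContext list with optional elements `rcs`, `gs`, `cvinv`,
#'   `qcoe`, each `c(min, max)` over the design round; NULL gives neutral
#'   normalization.
#' @return list of class `OptimizationScore` with `qs`, `rp`, `lip`,
#'   `allPeaks`, `gr`, `qcoe`, `rcsRaw`, `gsRaw`, `cvRaw`.
#' @export
computeQualityScore <- function(fs, replicateGroups = NULL, normContext = NULL) {
  stopifnot(is(fs, "FeatureSet"))
  ft <- fs@features
  allPeaks <- nrow(ft)
  rp <- sum(ft$hasIsotope, na.rm = TRUE)
  lip <- sum(ft$lowIntensityIsotope, na.rm = TRUE)
  gaussian <- sum(ft$gaussCor >= 0.9 & ft$gaussP <= 0.05, na.rm = TRUE)
  gr <- if (allPeaks > 0) gaussian / allPeaks else 0
  if (is.null(replicateGroups)) replicateGroups <- list(seq_len(fs@nSamples))
  cvRaw <- featureCv(fs@intensities, replicateGroups)
  rcsN <- unitNorm(fs@rcs, normContext$rcs)
  gsN <- unitNorm(fs@gs, normContext$gs)
  cvInvN <- if (is.na(cvRaw)) 0.5 else unitNorm(1 - cvRaw, normContext$cvinv)
  qcoe <- qcoeCombine(rcsN, gsN, cvInvN)
  if (!is.null(normContext$qcoe)) qcoe <- unitNorm(qcoe, normContext$qcoe)
  qcoe <- min(max(qcoe, 0), 1)
  structure(list(qs = qualityScore(rp, lip, allPeaks, gr, qcoe),
                 rp = rp, lip = lip, allPeaks = allPeaks, gr = gr,
                 qcoe = qcoe, rcsRaw = fs@rcs, gsRaw = fs@gs, cvRaw = cvRaw),
            class = "OptimizationScore")
}

# Median per-feature CV of intensities within replicate groups; NA when
# no group has >= 2 samples or no features.
featureCv <- function(intens, replicateGroups) {
  if (nrow(intens) == 0L) return(NA_real_)
  grps <- Filter(function(g) length(g) >= 2L, replicateGroups)
  if (!length(grps)) return(NA_real_)
  cvs <- apply(intens, 1, function(v) {
    g <- vapply(grps, function(idx) {
      m <- mean(v[idx])
      if (!is.finite(m) || m <= 0) return(NA_real_)
      stats::sd(v[idx]) / m
    }, numeric(1))
    mean(g, na.rm = TRUE)
  })
  cvs <- cvs[is.finite(cvs)]
  if (!length(cvs)) return(NA_real_)
  stats::median(cvs)
}

#' @export
print.OptimizationScore <- function(x, ...) {
  cat(sprintf("QS %.4g | RP %d, LIP %d, all %d, GR %.3f, QcoE %.3f\n",
              x$qs, x$rp, x$lip, x$allPeaks, x$gr, x$qcoe))
  invisible(x)
}
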