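# Benchmark computations: matching detected features to reference
# compounds, consensus quantification, dilution-series linearity counting
# and the Gaussian peak ratio.

#' Match detected features to reference compounds
#'
#' Greedy one-to-one nearest matching: candidate (feature, reference)
#' pairs within the m/z and RT tolerances are assigned in order of ppm
#' distance (RT difference breaks ties), each feature and each reference
#' used at most once.
#'
#' @param features data.frame with `mz`, `rt`.
#' @param reference data.frame with `id`, `mz`, `rt` and optionally
#'   `expectedRatio`.
#' @param ppmTol m/z tolerance, ppm (default 10).
#' @param rtTol RT tolerance, seconds (default 18, i.e. 0.3 min).
#' @return list with `matched` (data.frame `refId`, `feature` row index,
#'   `ppm`, `dRt`) and `unmatched` (reference ids).
#' @export
matchTruePeaks <- function(features, reference, ppmTol = 10, rtTol = 18) {
  stopifnot(nrow(features) > 0L, nrow(reference) > 0L)
  cand <- list()
  for (r in seq_len(nrow(reference))) {
    ppm <- abs(features$mz - reference$mz[r]) / reference$mz[r] * 1e6
    dRt <- abs(features$rt - reference$rt[r])
    hit <- which(ppm < ppmTol & dRt < rtTol)
    if (length(hit))
      cand[[length(cand) + 1L]] <- data.frame(refId = reference$id[r], ref = r,
                                              feature = hit, ppm = ppm[hit],
                                              dRt = dRt[hit])
  }
  if (!length(cand)) {
    return(list(matched = data.frame(refId = character(), feature = integer(),
                                     ppm = numeric(), dRt = numeric()),
                unmatched = reference$id))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$ppm, cand$dRt), ]
  usedF <- integer(0); usedR <- integer(0); keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (cand$feature[i] %in% usedF || cand$ref[i] %in% usedR) next
    keep <- c(keep, i)
    usedF <- c(usedF, cand$feature[i]); usedR <- c(usedR, cand$ref[i])
  }
  matched <- cand[keep, c("refId", "feature", "ppm", "dRt")]
  rownames(matched) <- NULL
  list(matched = matched,
       unmatched = setdiff(reference$id, matched$refId))
}

#' Count consensus-quantified matches
#'
#' A matched reference is consensus-quantified when the observed
#' between-group intensity ratio (mean of group A over mean of group B of
#' the matched feature's areas) is within `relErrTol` relative error of
#' the expected concentration ratio.
#'
#' @param matched the `matched` data.frame of [matchTruePeaks()].
#' @param reference the reference table carrying `id` and
#'   `expectedRatio`.
#' @param intensA,intensB numeric matrices (features x samples) or
#'   vectors of per-feature group means, rows aligned with the feature
#'   table the matching used.
#' @param relErrTol relative error tolerance (default 0.5).
#' @return list with `count` and `skipped` (zero group-B mean).
#' @export
consensusQuantified <- function(matched, reference, intensA, intensB,
                                relErrTol = 0.5) {
  meanOf <- function(x, i) if (is.matrix(x)) mean(x[i, ]) else x[i]
  count <- 0L; skipped <- 0L
  for (i in seq_len(nrow(matched))) {
    exp <- reference$expectedRatio[match(matched$refId[i], reference$id)]
    if (is.na(exp)) next
    ma <- meanOf(intensA, matched$feature[i])
    mb <- meanOf(intensB, matched$feature[i])
    if (!is.finite(mb) || mb == 0) { skipped <- skipped + 1L; next }
    if (abs((ma / mb) / exp - 1) < relErrTol) count <- count + 1L
  }
  list(count = count, skipped = skipped)
}

#' Count dilution-linear peaks
#'
#' Per feature, ordinary least squares of intensity against the dilution
#' factor; a feature is linear when the slope t-test p-value is below
#' `alpha` and the slope is positive. Constant features have no defined
#' test and are not counted.
#'
#' @param table features x runs intensity matrix.
#' @param factors dilution factor per run (>= 3 distinct values).
#' @param alpha significance threshold (default 0.001).
#' @return list with `nLinear` and `fraction`.
#' @export
countLinearPeaks <- function(table, factors, alpha = 0.001) {
  stopifnot(ncol(table) == length(factors))
  if (length(unique(factors)) < 3L) stop("need >= 3 distinct dilution factors")
  n <- 0L
  for (i in seq_len(nrow(table))) {
    y <- table[i, ]
    if (stats::sd(y) == 0) next
    fit <- stats::lm(y ~ factors)
    co <- suppressWarnings(summary(fit))$coefficients  # exact fits are legitimate
    if (nrow(co) < 2L || !is.finite(co[2, 4])) next
    if (co[2, 4] < alpha && co[2, 1] > 0) n <- n + 1L
  }
  list(nLinear = n, fraction = n / nrow(table))
}

#' Gaussian peak ratio of a feature table
#'
#' Fraction of features whose EIC Gaussian fit reached `cor >= 0.9` and
#' `p <= 0.05`. Features without a score count as non-Gaussian.
#'
#' @param features data.frame with `gaussCor`, `gaussP`.
#' @return fraction in [0, 1].
#' @export
gaussianPeakRatio <- function(features) {
  if (nrow(features) == 0L) stop("empty feature table")
  stopifnot(all(c("gaussCor", "gaussP") %in% names(features)))
  ok <- !is.na(features$gaussCor) & !is.na(features$gaussP) &
    features$gaussCor >= 0.9 & features$gaussP <= 0.05
  sum(ok) / nrow(features)
}
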