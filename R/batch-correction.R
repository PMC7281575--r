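# Batch-effect correction: three correctors spanning the main assumption
# classes (empirical-Bayes location/scale = ComBat; SVD bias removal =
# EigenMS; QC-anchored LOESS drift correction = QC-RLSC) plus the
# automatic selector that scores every feasible candidate by ordination-
# based inter-batch distance and returns the minimum.

halfMinImpute <- function(mat) {
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      pos <- v[!bad]
      fill <- if (length(pos)) min(pos) / 2 else 1
      mat[i, bad] <- fill
    }
  }
  mat
}

#' ComBat batch correction
#'
#' Parametric empirical-Bayes location/scale adjustment on the log scale
#' (via `sva::ComBat`), preserving biological group effects through a
#' design covariate, then back-transformed to the intensity scale.
#'
#' @param mat features x samples matrix of positive intensities (zeros
#'   are imputed to half the feature minimum).
#' @param design a [BatchDesign-class]; needs >= 2 samples per batch.
#' @return corrected matrix, same shape, positive.
#' @export
correctCombat <- function(mat, design) {
  stopifnot(is(design, "BatchDesign"), ncol(mat) == length(design))
  batch <- droplevels(design@batch)
  if (nlevels(batch) < 2L) {
    warning("single batch: ComBat is an identity")
    return(mat)
  }
  if (any(table(batch) < 2L)) stop("ComBat needs >= 2 samples per batch")
  L <- log(halfMinImpute(mat))
  grp <- droplevels(design@group)
  mod <- if (nlevels(grp) > 1L) stats::model.matrix(~grp) else NULL
  corrected <- suppressMessages(tryCatch(
    sva::ComBat(dat = L, batch = batch, mod = mod, par.prior = TRUE,
                prior.plots = FALSE),
    error = function(e) sva::ComBat(dat = L, batch = batch, mod = NULL,
                                    par.prior = TRUE, prior.plots = FALSE)))
  out <- exp(corrected)
  dimnames(out) <- dimnames(mat)
  pmax(out, .Machine$double.eps)
}

#' EigenMS-style SVD bias correction
#'
#' (1) log-transform; (2) remove known biological group effects per
#' feature (group-means model); (3) SVD of the residual matrix; (4) the
#' number of significant systematic-bias trends is chosen by a
#' permutation test on the leading singular values (within-row
#' permutations break sample structure; a trend is kept while its
#' singular value exceeds the `1 - alpha` quantile of permuted first
#' singular values); (5) the reconstructed bias is subtracted; (6) group
#' effects are re-added and the matrix back-transformed.
#'
#' @param mat features x samples positive matrix.
#' @param design a [BatchDesign-class] (group labels drive effect
#'   preservation).
#' @param alpha significance level of the permutation test.
#' @param nPerm number of permutations.
#' @param seed integer seed for the permutation draw.
#' @return corrected matrix; attribute `trendsRemoved` records the number
#'   of bias trends subtracted.
#' @export
correctEigenms <- function(mat, design, alpha = 0.05, nPerm = 99L, seed = 1L) {
  stopifnot(is(design, "BatchDesign"), ncol(mat) == length(design))
  L <- log(halfMinImpute(mat))
  grp <- droplevels(design@group)
  # per-feature group means
  fit <- matrix(0, nrow(L), ncol(L))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    fit[, idx] <- rowMeans(L[, idx, drop = FALSE])
  }
  R <- L - fit
  sv <- svd(R)
  maxTrends <- min(dim(R)) - 1L
  nullD1 <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    Rp <- t(apply(R, 1, sample))
    svd(Rp, nu = 0, nv = 0)$d[1]
  }, numeric(1)))
  thr <- stats::quantile(nullD1, 1 - alpha)
  nTrends <- 0L
  while (nTrends < maxTrends && sv$d[nTrends + 1L] > thr) nTrends <- nTrends + 1L
  if (nTrends > 0L) {
    bias <- sv$u[, seq_len(nTrends), drop = FALSE] %*%
      diag(sv$d[seq_len(nTrends)], nTrends) %*%
      t(sv$v[, seq_len(nTrends), drop = FALSE])
    R <- R - bias
  }
  out <- exp(fit + R)
  dimnames(out) <- dimnames(mat)
  structure(pmax(out, .Machine$double.eps), trendsRemoved = nTrends)
}

#' QC-based robust LOESS signal correction (QC-RLSC)
#'
#' Per feature, a LOESS curve is fitted to the QC intensities against
#' injection order; the correction factor for every sample is the fitted
#' QC trend (constant-extrapolated beyond the first/last QC) divided by
#' the median QC intensity, and intensities are divided by it. Features
#' with fewer than 3 finite QC values are left uncorrected and counted.
#'
#' @param mat features x samples positive matrix.
#' @param design a [BatchDesign-class] with >= 3 QC samples and injection
#'   order.
#' @param span LOESS span.
#' @return corrected matrix; attribute `skippedFeatures` counts features
#'   left uncorrected.
#' @export
correctQcrlsc <- function(mat, design, span = 0.75) {
  stopifnot(is(design, "BatchDesign"), ncol(mat) == length(design))
  qcIdx <- which(design@isQC)
  if (length(qcIdx) < 3L) stop("QC-RLSC needs >= 3 QC samples")
  ord <- design@injectionOrder
  out <- mat
  skipped <- 0L
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, qcIdx]
    ok <- is.finite(y) & y > 0
    if (sum(ok) < 3L) { skipped <- skipped + 1L; next }
    x <- ord[qcIdx][ok]; y <- y[ok]
    fit <- tryCatch(suppressWarnings(
      stats::loess(y ~ x, span = span, degree = 1, family = "gaussian",
                   control = stats::loess.control(surface = "direct"))),
      error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    xAll <- pmin(pmax(ord, min(x)), max(x))  # constant extrapolation
    trend <- stats::predict(fit, newdata = data.frame(x = xAll))
    fac <- trend / stats::median(y)
    fac[!is.finite(fac) | fac <= 0] <- 1
    out[i, ] <- mat[i, ] / fac
  }
  structure(pmax(out, .Machine$double.eps), skippedFeatures = skipped)
}

#' Gradient length of the first DCA axis
#'
#' Detrended correspondence analysis (reciprocal averaging with
#' detrending by 26 segments and Hill's nonlinear rescaling, via
#' `vegan::decorana`) of a samples x features abundance matrix; returns
#' the range of sample scores on the first axis in standard-deviation
#' units. Used to choose the ordination for correction scoring: PCA when
#' the gradient is longer than 3, CCA otherwise. Rank-deficient or tiny
#' matrices fall back to the range of unconstrained CA axis-1 scores with
#' a warning.
#'
#' @param mat samples x features non-negative matrix (no all-zero
#'   sample).
#' @return gradient length (non-negative scalar).
#' @export
gradientLength <- function(mat) {
  mat <- as.matrix(mat)
  if (any(rowSums(mat) <= 0)) stop("all-zero sample row")
  d <- tryCatch(suppressWarnings(vegan::decorana(mat)), error = function(e) NULL)
  if (!is.null(d)) {
    sc <- tryCatch(vegan::scores(d, display = "sites", choices = 1),
                   error = function(e) NULL)
    if (!is.null(sc) && all(is.finite(sc))) return(diff(range(sc)))
  }
  warning("DCA failed (tiny or rank-deficient matrix); falling back to CA axis 1")
  ca <- vegan::cca(mat)
  sc <- vegan::scores(ca, display = "sites", choices = 1)
  diff(range(sc))
}

#' Choose the scoring ordination from the DCA gradient length
#'
#' PCA when the first-axis gradient length exceeds 3, CCA otherwise (the
#' boundary value 3 itself selects CCA).
#'
#' @param gl gradient length from [gradientLength()].
#' @return `"PCA"` or `"CCA"`.
#' @export
chooseOrdination <- function(gl) if (gl > 3) "PCA" else "CCA"

#' Score a (corrected) table by inter-batch distance
#'
#' Chooses the ordination by the DCA gradient length of the raw
#' intensities (> 3: PCA of the standardized log matrix; otherwise CCA
#' constrained on batch), then scores the first two ordination axes with
#' two scale-normalized terms: (1) the chance-corrected mean pairwise
#' Euclidean distance between batch centroids - the mean centroid
#' distance under randomly permuted batch labels (20 seeded
#' permutations) is subtracted, flooring at 0, so that chance-level
#' batch structure scores ~0 and removing it is not rewarded -
#' normalized by the total score standard deviation; (2) when QCs exist,
#' the mean QC-to-QC-centroid distance normalized by the mean
#' biological-sample-to-centroid distance (pooled technical vs
#' biological dispersion, which cancels ordination-space rescaling).
#' Lower is better.
#'
#' @param mat features x samples positive matrix.
#' @param design a [BatchDesign-class].
#' @return list with `score`, `ordination` (`"PCA"` or `"CCA"`) and
#'   `gradientLength`.
#' @export
evaluateCorrection <- function(mat, design) {
  stopifnot(is(design, "BatchDesign"), ncol(mat) == length(design))
  imp <- halfMinImpute(mat)
  gl <- gradientLength(t(imp))
  ordination <- chooseOrdination(gl)
  L <- log(imp)
  keep <- apply(L, 1, stats::sd) > 0
  L <- L[keep, , drop = FALSE]
  batch <- droplevels(design@batch)
  # score space for a given batch labelling: CCA is refit per labelling
  # (its constrained axis overfits whatever labels it is given, so the
  # permutation null must include that overfit); PCA is label-free.
  spaceFor <- function(lab) {
    sc <- if (ordination == "PCA") {
      pc <- stats::prcomp(t(L), center = TRUE, scale. = TRUE)
      pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
    } else {
      tryCatch(
        vegan::scores(vegan::cca(t(imp) ~ lab), display = "sites",
                      choices = 1:2, scaling = 1),
        error = function(e) {
          pc <- stats::prcomp(t(L), center = TRUE, scale. = TRUE)
          pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
        })
    }
    as.matrix(sc)
  }
  # separation index: mean pairwise batch-centroid distance over the mean
  # within-batch point-to-centroid distance, in the space fit to `lab`
  sepIndex <- function(lab) {
    sc <- spaceFor(lab)
    cent <- rowsum(sc, lab) / as.vector(table(lab))
    within <- mean(sqrt(rowSums((sc - cent[as.integer(lab), , drop = FALSE])^2)))
    if (!is.finite(within) || within <= 0) within <- 1
    mean(stats::dist(cent)) / within
  }
  sc <- spaceFor(batch)
  score <- 0
  if (nlevels(batch) >= 2L) {
    obs <- sepIndex(batch)
    # chance reference = 95th percentile of the permutation null, so the
    # term is ~0 on null data rather than half-normal around 0
    chance <- withSeed(131071L, stats::quantile(vapply(seq_len(49L), function(b)
      sepIndex(sample(batch)), numeric(1)), 0.95))
    score <- score + max(0, obs - chance)
  }
  if (any(design@isQC) && sum(!design@isQC) >= 2L) {
    qs <- sc[design@isQC, , drop = FALSE]
    bs <- sc[!design@isQC, , drop = FALSE]
    qcDisp <- mean(sqrt(rowSums(sweep(qs, 2, colMeans(qs))^2)))
    bioDisp <- mean(sqrt(rowSums(sweep(bs, 2, colMeans(bs))^2)))
    if (is.finite(bioDisp) && bioDisp > 0)
      score <- score + qcDisp / bioDisp
  }
  list(score = score, ordination = ordination, gradientLength = gl)
}

#' Select the best batch-correction method
#'
#' Runs every feasible candidate corrector, scores each corrected table
#' with [evaluateCorrection()], and returns the minimum-score result.
#' Infeasible candidates (e.g. QC-RLSC without 3 QCs) are skipped and
#' logged. A corrector must improve on the uncorrected score by more
#' than `minImprovement` (relative), and by at least 0.1 absolute - the
#' magnitude of between-candidate score noise on null data at typical QC
#' counts - to displace "none": a parsimony guard against rewarding
#' overcorrection of chance structure on clean data. Ties among
#' improving correctors resolve by the precedence eigenms, combat,
#' qc_rlsc.
#'
#' @param mat features x samples positive matrix.
#' @param design a [BatchDesign-class].
#' @param candidates subset of `c("eigenms", "combat", "qc_rlsc",
#'   "none")`.
#' @param seed seed passed to the EigenMS permutation test.
#' @param minImprovement minimum relative score improvement over the
#'   uncorrected data for a corrector to be selected (default 0.05).
#' @return list of class `CorrectionResult`: `method`, `corrected`,
#'   `score`, `ordination`, `gradientLength`, `log` (per-candidate notes
#'   and scores).
#' @export
selectBestCorrection <- function(mat, design,
                                 candidates = c("eigenms", "combat", "qc_rlsc", "none"),
                                 seed = 1L, minImprovement = 0.1) {
  precedence <- c("eigenms", "combat", "qc_rlsc", "none")
  candidates <- unique(match.arg(candidates, precedence, several.ok = TRUE))
  log <- list()
  results <- list()
  for (m in precedence[precedence %in% candidates]) {
    corrected <- tryCatch(switch(m,
      none = mat,
      combat = suppressWarnings(correctCombat(mat, design)),
      eigenms = correctEigenms(mat, design, seed = seed),
      qc_rlsc = correctQcrlsc(mat, design)),
      error = function(e) e)
    if (inherits(corrected, "error")) {
      log[[m]] <- paste("skipped:", conditionMessage(corrected))
      next
    }
    ev <- evaluateCorrection(corrected, design)
    results[[m]] <- list(method = m, corrected = corrected, score = ev$score,
                         ordination = ev$ordination,
                         gradientLength = ev$gradientLength)
    log[[m]] <- sprintf("score %.4g (%s)", ev$score, ev$ordination)
  }
  if (!length(results)) {
    warning("no feasible correction candidate; returning identity")
    ev <- evaluateCorrection(mat, design)
    return(structure(list(method = "none", corrected = mat, score = ev$score,
                          ordination = ev$ordination,
                          gradientLength = ev$gradientLength, log = log),
                     class = "CorrectionResult"))
  }
  scores <- vapply(results, `[[`, numeric(1), "score")
  noneScore <- if ("none" %in% names(results)) results[["none"]]$score
               else evaluateCorrection(mat, design)$score
  improves <- (noneScore - scores) > pmax(minImprovement * noneScore, 0.1)
  best <- if (any(improves)) {
    # first minimum among improving candidates = precedence order
    cand <- results[improves]
    cand[[which.min(scores[improves])]]
  } else if ("none" %in% names(results)) {
    results[["none"]]
  } else {
    results[[which.min(scores)]]
  }
  structure(c(best, list(log = log)), class = "CorrectionResult")
}

#' @export
print.CorrectionResult <- function(x, ...) {
  cat(sprintf("CorrectionResult: method '%s', score %.4g (%s, gradient %.2f)\n",
              x$method, x$score, x$ordination, x$gradientLength))
  for (m in names(x$log)) cat(sprintf("  %s: %s\n", m, x$log[[m]]))
  invisible(x)
}
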