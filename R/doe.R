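# Box-Behnken design-of-experiments optimization of the five peak-picking
# parameters (peakwidthMin, peakwidthMax, mzdiff, snthresh, bw), with the
# noise floor, prefilter and ppm fixed up front from the data. The round
# loop fits a full quadratic response surface to the Quality Score,
# recenters on the surface optimum, and expands ranges that pin at the
# coded boundary.

DOE_FACTORS <- c("peakwidthMin", "peakwidthMax", "mzdiff", "snthresh", "bw")

#' Build a 5-factor Box-Behnken design
#'
#' Standard Box-Behnken construction for 5 factors: for every pair of
#' factors the four (+/-1, +/-1) combinations with the remaining factors
#' at 0 (40 edge runs), plus 6 center replicates (46 runs). Coded levels
#' map affinely onto the natural ranges. Rows whose decoded
#' `peakwidthMin` is not below `peakwidthMax` are repaired by swapping
#' the two values (recorded in `repairedRows`).
#'
#' @param ranges named list of `c(low, high)` for each of the five
#'   factors `peakwidthMin`, `peakwidthMax`, `mzdiff`, `snthresh`, `bw`.
#' @return list of class `DoEDesign` with `factors`, `ranges`, `coded`
#'   (46 x 5 matrix in {-1, 0, 1}), `natural` (decoded data.frame),
#'   `nCenter`, `repairedRows`.
#' @export
buildBBDesign <- function(ranges) {
  stopifnot(setequal(names(ranges), DOE_FACTORS))
  ranges <- ranges[DOE_FACTORS]
  for (f in DOE_FACTORS) {
    r <- ranges[[f]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("invalid range for ", f)
  }
  k <- 5L
  pairs <- utils::combn(k, 2)
  coded <- matrix(0, nrow = 4 * ncol(pairs) + 6, ncol = k,
                  dimnames = list(NULL, DOE_FACTORS))
  row <- 0L
  lv <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (p in seq_len(ncol(pairs))) {
    for (l in 1:4) {
      row <- row + 1L
      coded[row, pairs[1, p]] <- lv[l, 1]
      coded[row, pairs[2, p]] <- lv[l, 2]
    }
  }
  # remaining 6 rows are center replicates (all zero)
  center <- vapply(ranges, mean, numeric(1))
  half <- vapply(ranges, function(r) diff(r) / 2, numeric(1))
  natural <- as.data.frame(sweep(sweep(coded, 2, half, `*`), 2, center, `+`))
  repaired <- integer(0)
  for (i in seq_len(nrow(natural))) {
    if (natural$peakwidthMin[i] >= natural$peakwidthMax[i]) {
      tmp <- natural$peakwidthMin[i]
      natural$peakwidthMin[i] <- natural$peakwidthMax[i]
      natural$peakwidthMax[i] <- tmp
      if (natural$peakwidthMin[i] >= natural$peakwidthMax[i])  # equal widths
        natural$peakwidthMin[i] <- 0.8 * natural$peakwidthMax[i]
      repaired <- c(repaired, i)
    }
  }
  structure(list(factors = DOE_FACTORS, ranges = ranges, coded = coded,
                 natural = natural, nCenter = 6L, repairedRows = repaired),
            class = "DoEDesign")
}

#' Fit a quadratic response surface and locate its optimum
#'
#' Full second-order least-squares model (intercept, linear, two-way
#' interactions, pure quadratics) of the response over the coded design;
#' the optimum is the argmax of the fitted surface over the coded cube
#' `[-1, 1]^5`, found by box-constrained quasi-Newton refinement from the
#' cube corners, the center and the best observed point. Factors whose
#' optimum sits at |coded| > 0.95 are flagged `onBoundary`.
#'
#' @param design a `DoEDesign` from [buildBBDesign()].
#' @param responses numeric vector of responses, one per design row.
#' @return list with `model`, `optimumCoded`, `optimumNatural`,
#'   `onBoundary` (named logical), `nonInformative` (TRUE when all
#'   responses are equal and the center is returned).
#' @export
fitResponseSurface <- function(design, responses) {
  stopifnot(inherits(design, "DoEDesign"),
            length(responses) == nrow(design$coded))
  if (!all(is.finite(responses))) stop("responses must be finite")
  k <- length(design$factors)
  center <- vapply(design$ranges, mean, numeric(1))
  half <- vapply(design$ranges, function(r) diff(r) / 2, numeric(1))
  decode <- function(z) center + z * half
  if (max(responses) - min(responses) <= 0) {
    return(list(model = NULL, optimumCoded = stats::setNames(rep(0, k), design$factors),
                optimumNatural = decode(rep(0, k)),
                onBoundary = stats::setNames(rep(FALSE, k), design$factors),
                nonInformative = TRUE))
  }
  df <- as.data.frame(design$coded)
  names(df) <- paste0("x", seq_len(k))
  df$y <- responses
  fml <- stats::as.formula(paste(
    "y ~ (", paste(names(df)[1:k], collapse = "+"), ")^2 +",
    paste(sprintf("I(x%d^2)", seq_len(k)), collapse = "+")))
  model <- stats::lm(fml, data = df)
  predCoded <- function(z) {
    nd <- as.data.frame(as.list(stats::setNames(z, paste0("x", seq_len(k)))))
    as.numeric(stats::predict(model, newdata = nd))
  }
  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  bestObs <- design$coded[which.max(responses), ]
  starts <- rbind(corners, rep(0, k), bestObs)
  bestZ <- rep(0, k); bestV <- -Inf
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(stats::optim(starts[i, ], function(z) -predCoded(z),
                                 method = "L-BFGS-B",
                                 lower = rep(-1, k), upper = rep(1, k)),
                    error = function(e) NULL)
    if (!is.null(opt) && -opt$value > bestV) { bestV <- -opt$value; bestZ <- opt$par }
  }
  onB <- stats::setNames(abs(bestZ) > 0.95, design$factors)
  list(model = model,
       optimumCoded = stats::setNames(bestZ, design$factors),
       optimumNatural = decode(bestZ),
       onBoundary = onB, nonInformative = FALSE)
}

#' Initial peak-picking parameters per LC-MS platform
#'
#' Registry of documented starting [PickerParams-class] for common
#' platform classes; these are this package's defaults chosen by the
#' usual instrument characteristics (Orbitrap-class instruments get tight
#' ppm, TOF-class intermediate, ion traps loose; HPLC gradients get wider
#' peak-width windows than UPLC).
#'
#' @param name one of `"UPLC-Q/E"`, `"UPLC-Q/TOF"`, `"UPLC-T/TOF"`,
#'   `"UPLC-Ion_trap"`, `"UPLC-G2-S"`, `"HPLC-Q/TOF"`, `"HPLC-Ion_trap"`,
#'   `"HPLC-Orbitrap"`, `"HPLC-S/Q"`, `"generic"`.
#' @return a [PickerParams-class].
#' @export
platformDefaults <- function(name = "generic") {
  reg <- list(
    "UPLC-Q/E"      = PickerParams(ppm = 5,  peakwidthMin = 4,  peakwidthMax = 20, mzdiff = 0.01, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 2),
    "UPLC-Q/TOF"    = PickerParams(ppm = 15, peakwidthMin = 4,  peakwidthMax = 20, mzdiff = 0.01, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 2),
    "UPLC-T/TOF"    = PickerParams(ppm = 15, peakwidthMin = 4,  peakwidthMax = 20, mzdiff = 0.01, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 2),
    "UPLC-Ion_trap" = PickerParams(ppm = 50, peakwidthMin = 4,  peakwidthMax = 30, mzdiff = 0.05, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 3),
    "UPLC-G2-S"     = PickerParams(ppm = 15, peakwidthMin = 4,  peakwidthMax = 20, mzdiff = 0.01, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 2),
    "HPLC-Q/TOF"    = PickerParams(ppm = 15, peakwidthMin = 8,  peakwidthMax = 45, mzdiff = 0.01, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 5),
    "HPLC-Ion_trap" = PickerParams(ppm = 50, peakwidthMin = 8,  peakwidthMax = 45, mzdiff = 0.05, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 5),
    "HPLC-Orbitrap" = PickerParams(ppm = 5,  peakwidthMin = 8,  peakwidthMax = 45, mzdiff = 0.01, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 5),
    "HPLC-S/Q"      = PickerParams(ppm = 30, peakwidthMin = 8,  peakwidthMax = 45, mzdiff = 0.05, snthresh = 6, noise = 100, prefilterK = 3, prefilterI = 100, bw = 5),
    "generic"       = PickerParams(ppm = 30, peakwidthMin = 3,  peakwidthMax = 60, mzdiff = 0.01, snthresh = 3, noise = 50,  prefilterK = 2, prefilterI = 50,  bw = 5)
  )
  if (!name %in% names(reg))
    stop("unknown platform '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Evaluate one parameter point on a set of runs
#'
#' Runs the full pick / group / isotope-flag chain with the given
#' parameters and computes the Quality Score components. The returned
#' `score` uses a neutral quality-coefficient normalization (every QcoE
#' component at 0.5), which makes scores of different parameter sets
#' directly comparable outside a design round.
#'
#' @param runs list of [SpectraRun-class].
#' @param params a [PickerParams-class].
#' @param replicateGroups list of sample-index vectors for the CV term.
#' @return list with `fs` (the [FeatureSet-class]), `score` (an
#'   `OptimizationScore` under neutral normalization) and the raw
#'   components `rcsRaw`, `gsRaw`, `cvRaw`, `rp`, `lip`, `allPeaks`,
#'   `gr`.
#' @export
evaluatePickerParams <- function(runs, params, replicateGroups = NULL) {
  peaks <- lapply(runs, pickPeaks, params = params)
  fs <- groupAndAlign(peaks, params)
  fs <- detectIsotopes(fs, ppm = max(params@ppm, 10))
  sc <- computeQualityScore(fs, replicateGroups = replicateGroups)
  list(fs = fs, score = sc, rcsRaw = sc$rcsRaw, gsRaw = sc$gsRaw,
       cvRaw = sc$cvRaw, rp = sc$rp, lip = sc$lip, allPeaks = sc$allPeaks,
       gr = sc$gr)
}

# Normalization context (min/max of raw RCS, GS, 1-CV) over a round of
# evaluations, plus the pre-rescaling QcoE range.
roundNormContext <- function(evals) {
  rng <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L || max(x) - min(x) <= 0) NULL else range(x)
  }
  rcs <- rng(vapply(evals, `[[`, numeric(1), "rcsRaw"))
  gs <- rng(vapply(evals, `[[`, numeric(1), "gsRaw"))
  cvinv <- rng(1 - vapply(evals, `[[`, numeric(1), "cvRaw"))
  ctx <- list(rcs = rcs, gs = gs, cvinv = cvinv)
  pre <- vapply(evals, function(e) {
    qcoeCombine(unitNorm(e$rcsRaw, ctx$rcs), unitNorm(e$gsRaw, ctx$gs),
                if (is.na(e$cvRaw)) 0.5 else unitNorm(1 - e$cvRaw, ctx$cvinv))
  }, numeric(1))
  ctx$qcoe <- if (max(pre) - min(pre) > 0) range(pre) else NULL
  ctx
}

scoreEval <- function(e, ctx) {
  rcsN <- unitNorm(e$rcsRaw, ctx$rcs)
  gsN <- unitNorm(e$gsRaw, ctx$gs)
  cvInvN <- if (is.na(e$cvRaw)) 0.5 else unitNorm(1 - e$cvRaw, ctx$cvinv)
  qcoe <- qcoeCombine(rcsN, gsN, cvInvN)
  if (!is.null(ctx$qcoe)) qcoe <- unitNorm(qcoe, ctx$qcoe)
  qualityScore(e$rp, e$lip, e$allPeaks, e$gr, qcoe)
}

#' Optimize peak-picking parameters by Box-Behnken DoE
#'
#' Round loop: (a) the noise floor, prefilter and ppm are fixed once from
#' the pooled per-run estimates ([estimateNoiseAndPpm()], medians across
#' runs); (b) a Box-Behnken design over the five remaining factors is
#' centered on the current best parameters; (c) the Quality Score is
#' evaluated at every design point (evaluations are independent); (d) a
#' quadratic response surface is fitted and the search recenters on its
#' optimum; (e) any factor pinned at the coded boundary has its range
#' shifted/expanded by 50% for the next round. The loop stops when the
#' relative improvement of the round's best QS drops below `relTol` or
#' after `maxRounds`. The returned parameters are the best evaluated
#' point, not the surface prediction; the initial parameter set is
#' itself evaluated as the incumbent, so the result is never worse than
#' the starting point. Within a round the response variable uses the
#' round-normalized quality coefficient; across rounds (and against the
#' incumbent) points are compared by the neutral-normalized score, which
#' is cohort-independent.
#'
#' @param trimmedRuns list of [SpectraRun-class] (typically ROI-trimmed;
#'   two or more runs recommended so the CV term is informative).
#' @param init starting [PickerParams-class] (e.g. [platformDefaults()]).
#' @param maxRounds maximum DoE rounds.
#' @param relTol relative QS improvement below which the loop converges.
#' @return list of class `OptimizationResult`: `bestParams`
#'   ([PickerParams-class]), `bestScore` (`OptimizationScore`),
#'   `history` (per round: design, responses, surface optimum, norm
#'   context), `converged`, `fixed` (the noise/prefilter/ppm estimates).
#' @export
optimizeParams <- function(trimmedRuns, init = platformDefaults("generic"),
                           maxRounds = 6L, relTol = 0.05) {
  stopifnot(length(trimmedRuns) >= 1L, is(init, "PickerParams"))
  est <- lapply(trimmedRuns, function(r)
    tryCatch(suppressWarnings(estimateNoiseAndPpm(r)), error = function(e) NULL))
  est <- Filter(Negate(is.null), est)
  fixed <- if (length(est)) {
    list(noise = stats::median(vapply(est, `[[`, numeric(1), "noise")),
         prefilterK = max(2L, min(10L, round(stats::median(
           vapply(est, `[[`, numeric(1), "prefilterK"))))),
         prefilterI = stats::median(vapply(est, `[[`, numeric(1), "prefilterI")),
         ppm = stats::median(vapply(est, `[[`, numeric(1), "ppm")))
  } else {
    list(noise = init@noise, prefilterK = init@prefilterK,
         prefilterI = init@prefilterI, ppm = init@ppm)
  }
  replicateGroups <- list(seq_along(trimmedRuns))
  centerP <- paramsAsList(init)
  centerP[names(fixed)] <- fixed
  spread <- list(peakwidthMin = 0.6, peakwidthMax = 0.6, mzdiff = 0.8,
                 snthresh = 0.6, bw = 0.6)
  ranges <- stats::setNames(lapply(DOE_FACTORS, function(f) {
    v <- centerP[[f]]
    c(v * (1 - spread[[f]]), v * (1 + spread[[f]]))
  }), DOE_FACTORS)
  clampRanges <- function(r) {
    r$peakwidthMin[1] <- max(r$peakwidthMin[1], 0.5)
    r$peakwidthMax[1] <- max(r$peakwidthMax[1], r$peakwidthMin[1] + 0.5)
    r$mzdiff[1] <- max(r$mzdiff[1], 1e-4)
    r$snthresh[1] <- max(r$snthresh[1], 0)
    r$bw[1] <- max(r$bw[1], 0.25)
    for (f in DOE_FACTORS) if (r[[f]][2] <= r[[f]][1]) r[[f]][2] <- r[[f]][1] * 1.5 + 0.5
    r
  }
  history <- list()
  # the init point itself is the incumbent: the search never returns
  # parameters whose (neutral-normalized, cross-round comparable) QS
  # falls below it
  initEval <- evaluatePickerParams(trimmedRuns, init, replicateGroups)
  bestQs <- initEval$score$qs
  bestParams <- init
  prevBest <- NA_real_; converged <- FALSE
  for (round in seq_len(maxRounds)) {
    ranges <- clampRanges(ranges)
    design <- buildBBDesign(ranges)
    evals <- vector("list", nrow(design$natural))
    for (i in seq_len(nrow(design$natural))) {
      pl <- centerP
      for (f in DOE_FACTORS) pl[[f]] <- design$natural[i, f]
      p <- tryCatch(paramsFromList(pl), error = function(e) NULL)
      evals[[i]] <- if (is.null(p)) {
        list(fs = NULL, rcsRaw = 0, gsRaw = 0, cvRaw = NA_real_,
             rp = 0, lip = 0, allPeaks = 0, gr = 0)
      } else evaluatePickerParams(trimmedRuns, p, replicateGroups)
    }
    ctx <- roundNormContext(evals)
    # round-context QS is the response-surface variable; the neutral QS
    # (comparable across rounds and to the incumbent) drives best tracking
    qs <- vapply(seq_along(evals), function(i) scoreEval(evals[[i]], ctx), numeric(1))
    qsNeutral <- vapply(evals, function(e)
      if (is.null(e$score)) 0 else e$score$qs, numeric(1))
    surf <- fitResponseSurface(design, qs)
    roundBestIdx <- which.max(qsNeutral)
    if (qsNeutral[roundBestIdx] > bestQs) {
      bestQs <- qsNeutral[roundBestIdx]
      pl <- centerP
      for (f in DOE_FACTORS) pl[[f]] <- design$natural[roundBestIdx, f]
      bestParams <- paramsFromList(pl)
    }
    history[[round]] <- list(design = design, responses = qs,
                             responsesNeutral = qsNeutral,
                             surfaceOptimum = surf$optimumNatural,
                             onBoundary = surf$onBoundary,
                             normContext = ctx, bestQs = max(qsNeutral))
    if (is.finite(prevBest) && prevBest > 0 &&
        (max(qsNeutral) - prevBest) / prevBest < relTol) {
      converged <- TRUE
      break
    }
    prevBest <- max(max(qsNeutral), prevBest, na.rm = TRUE)
    # recenter on the surface optimum; expand boundary-pinned ranges by 50%
    newCenter <- surf$optimumNatural
    for (f in DOE_FACTORS) {
      halfw <- diff(ranges[[f]]) / 2
      if (isTRUE(surf$onBoundary[[f]])) halfw <- halfw * 1.5
      ranges[[f]] <- c(newCenter[[f]] - halfw, newCenter[[f]] + halfw)
    }
  }
  if (!is.finite(bestQs) || bestQs <= 0)
    stop("every evaluated point scored QS = 0; use larger ROIs or a looser ",
         "initial parameter set")
  bestEval <- evaluatePickerParams(trimmedRuns, bestParams, replicateGroups)
  structure(list(bestParams = bestParams, bestScore = bestEval$score,
                 history = history, converged = converged, fixed = fixed),
            class = "OptimizationResult")
}

#' @export
print.OptimizationResult <- function(x, ...) {
  cat(sprintf("OptimizationResult: %d round(s), converged = %s, best QS %.4g\n",
              length(x$history), x$converged, x$bestScore$qs))
  print(x$bestParams)
  invisible(x)
}
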