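# centWave-style chromatographic peak detection, Gaussian shape scoring,
# cross-sample grouping/alignment and isotope annotation. This is the
# engine the DoE optimizer drives; it exposes the standard parameter
# vector (ppm, peakwidth, mzdiff, snthresh, noise, prefilter, bw) but is
# an independent implementation validated against planted ground truth.

#' Estimate noise floor, prefilter and ppm from a run
#'
#' Kernel-density-based instrument characterization: the noise floor is
#' the intensity at the first antimode of a kernel density estimate of
#' log10 intensities (the valley separating the noise mode from the
#' signal mode); `prefilterI` is set to that floor and `prefilterK` to
#' the modal consecutive-scan length of above-floor m/z traces; `ppm` is
#' the 95th percentile of within-trace deviations from each trace's
#' intensity-weighted mean m/z.
#'
#' @param run a non-empty [SpectraRun-class].
#' @param ppmFloor lower bound for the ppm estimate (instrument jitter is
#'   never reported as exactly zero).
#' @return list with `noise`, `prefilterK`, `prefilterI`, `ppm` and
#'   `fallback` (TRUE when the density had no antimode and the floor fell
#'   back to 3x the median intensity).
#' @export
estimateNoiseAndPpm <- function(run, ppmFloor = 1) {
  pts <- poolPoints(run)
  if (nrow(pts) == 0L) stop("empty run")
  li <- log10(pts$intensity[pts$intensity > 0])
  fallback <- FALSE
  noise <- NA_real_
  if (length(li) >= 10 && stats::sd(li) > 0) {
    d <- stats::density(li, n = 512)
    y <- d$y; ny <- length(y)
    isMax <- y > c(-Inf, y[-ny]) & y >= c(y[-1], -Inf)
    # the noise population is the dominant mode; a signal mode must exist
    # beyond it (>= 2% of the peak density) for an antimode to separate them
    m0 <- which.max(y)
    signalModes <- which(isMax & seq_len(ny) > m0 & y >= 0.02 * y[m0])
    if (length(signalModes)) {
      mEnd <- signalModes[length(signalModes)]
      valley <- m0 + which.min(y[m0:mEnd]) - 1L
      if (valley > m0 && valley < mEnd) noise <- 10^d$x[valley]
    }
  }
  if (!is.finite(noise)) {
    fallback <- TRUE
    noise <- 3 * stats::median(pts$intensity)
    warning("no noise/signal antimode in the intensity density; ",
            "noise floor fell back to 3x median intensity")
  }
  # ppm and prefilter statistics come from above-noise traces only
  sig <- pts[pts$intensity >= noise, , drop = FALSE]
  runLens <- integer(0)
  ppmDev <- numeric(0)
  if (nrow(sig) >= 3L) {
    for (t in buildTraces(sig, ppm = 50)) {
      if (nrow(t) < 3L) next
      sIdx <- sort(unique(t$scan))
      r <- rle(diff(sIdx) == 1L)
      if (any(r$values)) runLens <- c(runLens, r$lengths[r$values] + 1L)
      if (nrow(t) >= 5L) {
        wm <- sum(t$mz * t$intensity) / sum(t$intensity)
        ppmDev <- c(ppmDev, abs(t$mz - wm) / wm * 1e6)
      }
    }
  }
  k <- if (length(runLens)) {
    tb <- table(runLens)
    as.integer(names(tb)[which.max(tb)])
  } else 3L
  ppm <- if (length(ppmDev)) max(stats::quantile(ppmDev, 0.95), ppmFloor) else ppmFloor
  list(noise = noise, prefilterK = max(2L, min(10L, k)), prefilterI = noise,
       ppm = as.numeric(ppm), fallback = fallback)
}

# Chain pooled centroids into m/z traces: sort by m/z and split where the
# gap between neighbours exceeds the ppm tolerance. Returns a list of
# integer index vectors into `pts` (cheap; no data.frame copies). Points
# of one scan falling in the same trace are summed per scan downstream.
traceIndices <- function(mz, ppm) {
  n <- length(mz)
  if (n == 0L) return(list())
  o <- order(mz)
  ms <- mz[o]
  gap <- diff(ms)
  tol <- pmax(ppm * 1e-6 * ms[-n], 1e-5)
  id <- cumsum(c(1L, as.integer(gap > tol)))
  unname(split(o, id))
}

buildTraces <- function(pts, ppm) {
  lapply(traceIndices(pts$mz, ppm), function(i) pts[i, , drop = FALSE])
}

#' Fit a Gaussian to an EIC and score the shape
#'
#' Nonlinear least-squares fit of `h * exp(-(t - mu)^2 / (2 sigma^2))` to
#' an extracted ion chromatogram; the shape score is the Pearson
#' correlation between fitted and observed intensities together with the
#' two-sided correlation-test p-value. A peak is called Gaussian when
#' `cor >= 0.9` and `p <= 0.05`.
#'
#' @param rt,intensity numeric vectors (at least 4 points).
#' @return list with `cor` and `p`; non-convergence or degenerate input
#'   yields `cor = 0`, `p = 1`.
#' @export
scoreGaussian <- function(rt, intensity) {
  n <- length(rt)
  if (n < 4L || stats::sd(intensity) == 0) return(list(cor = 0, p = 1))
  iMax <- which.max(intensity)
  start <- list(h = intensity[iMax], mu = rt[iMax],
                sigma = max((max(rt) - min(rt)) / 4, 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ h * exp(-(t - mu)^2 / (2 * sigma^2)),
                      data = data.frame(t = rt, y = intensity),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(cor = 0, p = 1))
  fy <- stats::fitted(fit)
  if (stats::sd(fy) == 0) return(list(cor = 0, p = 1))
  r <- stats::cor(fy, intensity)
  if (!is.finite(r)) return(list(cor = 0, p = 1))
  r2 <- min(r^2, 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  list(cor = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Detect chromatographic peaks in one run
#'
#' centWave-style detection: (1) pooled centroids are chained into m/z
#' traces within the `ppm` tolerance; (2) traces must contain at least
#' `prefilterK` consecutive scans above `prefilterI` counts and an apex
#' above `noise`; (3) apexes are located on a Gaussian-smoothed EIC and
#' peak bounds delimited at flanking valleys / baseline; (4) peaks are
#' kept when their base width lies in `[peakwidthMin, peakwidthMax]` and
#' the signal-to-noise ratio reaches `snthresh`; (5) peaks closer than
#' `mzdiff` in m/z with overlapping RT ranges are merged; (6) each peak's
#' EIC is scored with [scoreGaussian()]. Deterministic.
#'
#' @param run a centroided MS1 [SpectraRun-class].
#' @param params a [PickerParams-class].
#' @return data.frame of peaks: `mz`, `mzmin`, `mzmax`, `rt`, `rtmin`,
#'   `rtmax`, `area` (counts*s, trapezoidal), `apexHeight`, `sn`,
#'   `gaussCor`, `gaussP`, `sample` (always 1 here; set by callers).
#'   Zero rows when nothing passes the filters.
#' @export
pickPeaks <- function(run, params = PickerParams()) {
  stopifnot(is(run, "SpectraRun"), is(params, "PickerParams"))
  empty <- data.frame(mz = numeric(), mzmin = numeric(), mzmax = numeric(),
                      rt = numeric(), rtmin = numeric(), rtmax = numeric(),
                      area = numeric(), apexHeight = numeric(), sn = numeric(),
                      gaussCor = numeric(), gaussP = numeric(), sample = integer())
  pts <- poolPoints(run)
  if (nrow(pts) == 0L) return(empty)
  scanRts <- sort(unique(pts$rt))
  ptScan <- match(pts$rt, scanRts)
  ptMz <- pts$mz; ptInt <- pts$intensity
  step <- if (length(scanRts) > 1L) stats::median(diff(scanRts)) else 1
  traces <- traceIndices(ptMz, params@ppm)
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 256L); acc$n <- 0L
  pushPeak <- function(v) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$rows)) acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    acc$rows[[acc$n]] <- v
  }
  for (ti in traces) {
    # per-scan EIC over the trace's scan range
    agg <- rowsum(cbind(ptInt[ti], ptMz[ti] * ptInt[ti]), ptScan[ti])
    sIdx <- as.integer(rownames(agg))
    lo <- min(sIdx); hi <- max(sIdx)
    eic <- numeric(hi - lo + 1L)
    eicMz <- rep(NA_real_, hi - lo + 1L)
    eic[sIdx - lo + 1L] <- agg[, 1]
    eicMz[sIdx - lo + 1L] <- agg[, 2] / agg[, 1]
    rts <- scanRts[lo:hi]
    # prefilter: >= K consecutive scans >= I, apex >= noise
    above <- eic >= params@prefilterI
    r <- rle(above)
    if (!any(r$values & r$lengths >= params@prefilterK)) next
    if (max(eic) < params@noise) next
    # smooth with a Gaussian kernel sized from the minimum peak width
    ksd <- max(1, params@peakwidthMin / (4 * step))
    kr <- ceiling(3 * ksd)
    kern <- stats::dnorm(-kr:kr, sd = ksd)
    kern <- kern / sum(kern)
    sm <- if (length(eic) > 2 * kr) {
      as.numeric(stats::filter(c(rep(0, kr), eic, rep(0, kr)), kern,
                               sides = 2))[(kr + 1):(kr + length(eic))]
    } else eic
    sm[is.na(sm)] <- 0
    n <- length(sm)
    isApex <- sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & eic >= params@noise
    apexes <- which(isApex)
    if (!length(apexes)) next
    for (a in apexes) {
      apexI <- eic[a]
      if (apexI < params@noise) next
      floorI <- max(0.02 * apexI, 1e-9)
      # walk out to valleys or baseline
      left <- a
      while (left > 1 && !(sm[left - 1] > sm[left] && eic[left] < 0.8 * apexI) &&
             eic[left - 1] > floorI) left <- left - 1
      right <- a
      while (right < n && !(sm[right + 1] > sm[right] && eic[right] < 0.8 * apexI) &&
             eic[right + 1] > floorI) right <- right + 1
      if (right - left < 2L) next
      width <- rts[right] - rts[left]
      if (width < params@peakwidthMin || width > params@peakwidthMax) next
      seg <- left:right
      baseline <- min(eic[left], eic[right])
      outside <- eic[-seg]
      outside <- outside[outside > 0]
      noiseLocal <- if (length(outside) >= 3) {
        max(stats::mad(outside), stats::median(outside), 1)
      } else max(params@noise / 2, 1)
      sn <- (apexI - baseline) / noiseLocal
      if (sn < params@snthresh) next
      segOn <- seg[eic[seg] > 0]
      if (length(segOn) < 3L) next
      area <- sum(diff(rts[seg]) * (eic[seg][-1] + eic[seg][-length(seg)]) / 2)
      wmz <- sum(eicMz[segOn] * eic[segOn], na.rm = TRUE) / sum(eic[segOn])
      g <- scoreGaussian(rts[segOn], eic[segOn])
      pushPeak(c(wmz, min(eicMz[segOn], na.rm = TRUE),
                 max(eicMz[segOn], na.rm = TRUE),
                 rts[a], rts[left], rts[right],
                 area, apexI, sn, g$cor, g$p))
    }
  }
  if (acc$n == 0L) return(empty)
  m <- do.call(rbind, acc$rows[seq_len(acc$n)])
  peaks <- data.frame(mz = m[, 1], mzmin = m[, 2], mzmax = m[, 3],
                      rt = m[, 4], rtmin = m[, 5], rtmax = m[, 6],
                      area = m[, 7], apexHeight = m[, 8], sn = m[, 9],
                      gaussCor = m[, 10], gaussP = m[, 11], sample = 1L)
  mergePeaksByMzdiff(peaks, params@mzdiff)
}

# Merge peaks closer than mzdiff in m/z with overlapping RT ranges: the
# most intense apex carries the consensus mz/rt; areas add; bounds union.
mergePeaksByMzdiff <- function(peaks, mzdiff) {
  if (nrow(peaks) <= 1L) return(peaks)
  o <- order(peaks$mz)
  peaks <- peaks[o, , drop = FALSE]
  grp <- seq_len(nrow(peaks))
  for (i in 2:nrow(peaks)) {
    for (j in (i - 1):1) {
      if (peaks$mz[i] - peaks$mz[j] >= mzdiff) break
      if (peaks$rtmin[i] <= peaks$rtmax[j] && peaks$rtmax[i] >= peaks$rtmin[j]) {
        grp[grp == grp[i]] <- grp[j]
        break
      }
    }
  }
  merged <- lapply(split(seq_len(nrow(peaks)), grp), function(idx) {
    if (length(idx) == 1L) return(peaks[idx, , drop = FALSE])
    sub <- peaks[idx, , drop = FALSE]
    top <- which.max(sub$apexHeight)
    res <- sub[top, , drop = FALSE]
    res$mzmin <- min(sub$mzmin); res$mzmax <- max(sub$mzmax)
    res$rtmin <- min(sub$rtmin); res$rtmax <- max(sub$rtmax)
    res$area <- sum(sub$area)
    res
  })
  res <- do.call(rbind, merged)
  res <- res[order(res$mz, res$rt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Group and align peaks across samples
#'
#' Density-based correspondence: peaks are pooled, sliced in m/z (slice
#' width `max(mzdiff, 2 * ppm * mz * 1e-6)`), and within each slice a
#' Gaussian kernel density over retention time with bandwidth `bw`
#' defines feature regions between flanking density minima. Each region
#' keeps at most one peak per sample (the most intense); leftover peaks
#' become singleton features. Well-behaved groups (present in at least
#' `minfrac` of samples, exactly one peak per sample) drive a per-sample
#' LOESS retention-time correction; the retention-time correction score
#' is `rcs = 1 / (1 + mean |post-alignment residual|)` and the grouping
#' score is `gs = good^2 / (bad + 1)`.
#'
#' @param peaksBySample list of per-sample peak tables from [pickPeaks()].
#' @param params a [PickerParams-class] (uses `ppm`, `mzdiff`, `bw`,
#'   `minfrac`).
#' @return a [FeatureSet-class].
#' @export
groupAndAlign <- function(peaksBySample, params = PickerParams()) {
  stopifnot(length(peaksBySample) >= 1L)
  nS <- length(peaksBySample)
  for (i in seq_len(nS)) {
    if (nrow(peaksBySample[[i]])) peaksBySample[[i]]$sample <- i
  }
  all <- do.call(rbind, peaksBySample[vapply(peaksBySample, nrow, integer(1)) > 0])
  if (is.null(all) || nrow(all) == 0L) {
    return(FeatureSet(data.frame(mz = numeric(), rt = numeric(),
                                 gaussCor = numeric(), gaussP = numeric(),
                                 hasIsotope = logical(), lowIntensityIsotope = logical()),
                      intensities = matrix(0, 0, nS), rcs = 1, gs = 0,
                      nSamples = nS))
  }
  groups <- sliceAndGroup(all, params)
  # alignment on well-behaved groups; a group must span more than one
  # sample to say anything about correspondence (unless only one exists)
  need <- if (nS == 1L) 1L else max(2L, ceiling(params@minfrac * nS))
  wellBehaved <- vapply(groups, function(g) {
    smp <- all$sample[g]
    length(unique(smp)) >= need && !anyDuplicated(smp)
  }, logical(1))
  good <- sum(wellBehaved); bad <- length(groups) - good
  rtCorrected <- all$rt
  if (nS > 1L && good >= 1L) {
    # per-group median rt as the alignment anchor
    anchors <- vapply(groups[wellBehaved], function(g) stats::median(all$rt[g]), numeric(1))
    for (s in seq_len(nS)) {
      rows <- integer(0); dev <- numeric(0)
      gi <- 0L
      for (g in groups[wellBehaved]) {
        gi <- gi + 1L
        hit <- g[all$sample[g] == s]
        if (length(hit) == 1L) {
          rows <- c(rows, hit)
          dev <- c(dev, all$rt[hit] - anchors[gi])
        }
      }
      if (length(rows) == 0L) next
      sAll <- which(all$sample == s)
      shift <- if (length(rows) >= 5L && stats::sd(all$rt[rows]) > 0 &&
                   stats::sd(dev) > 1e-9) {
        fit <- tryCatch(suppressWarnings(
          stats::loess(dev ~ rt, data = data.frame(rt = all$rt[rows], dev = dev),
                       span = 1, degree = 1,
                       control = stats::loess.control(surface = "direct"))),
          error = function(e) NULL)
        if (is.null(fit)) rep(stats::median(dev), length(sAll))
        else {
          rtc <- pmin(pmax(all$rt[sAll], min(all$rt[rows])), max(all$rt[rows]))
          pr <- suppressWarnings(stats::predict(fit, newdata = data.frame(rt = rtc)))
          pr[!is.finite(pr)] <- stats::median(dev)
          pr
        }
      } else rep(stats::median(dev), length(sAll))
      rtCorrected[sAll] <- all$rt[sAll] - shift
    }
  }
  # post-alignment residuals over well-behaved groups
  resid <- numeric(0)
  for (g in groups[wellBehaved]) {
    if (length(g) < 2L) next
    med <- stats::median(rtCorrected[g])
    resid <- c(resid, abs(rtCorrected[g] - med))
  }
  rcs <- 1 / (1 + if (length(resid)) mean(resid) else 0)
  gs <- good^2 / (bad + 1)
  # features: one per group, <= 1 member per sample (most intense area wins);
  # leftover same-sample peaks become singleton features
  featRows <- list(); members <- list(); intens <- list()
  addFeature <- function(idx) {
    sub <- all[idx, , drop = FALSE]
    top <- which.max(sub$area)
    featRows[[length(featRows) + 1L]] <<- data.frame(
      mz = stats::median(sub$mz), rt = stats::median(rtCorrected[idx]),
      gaussCor = sub$gaussCor[top], gaussP = sub$gaussP[top],
      hasIsotope = FALSE, lowIntensityIsotope = FALSE)
    members[[length(members) + 1L]] <<- sub
    v <- numeric(nS)
    v[sub$sample] <- sub$area
    intens[[length(intens) + 1L]] <<- v
  }
  for (g in groups) {
    smp <- all$sample[g]
    keep <- integer(0)
    for (s in unique(smp)) {
      cand <- g[smp == s]
      best <- cand[which.max(all$area[cand])]
      keep <- c(keep, best)
    }
    addFeature(keep)
    leftover <- setdiff(g, keep)
    for (l in leftover) addFeature(l)
  }
  FeatureSet(do.call(rbind, featRows),
             intensities = do.call(rbind, intens),
             members = members, rcs = rcs, gs = gs, nSamples = as.integer(nS))
}

# m/z slicing + per-slice RT kernel density grouping. Returns a list of
# integer index vectors into `all`.
sliceAndGroup <- function(all, params) {
  o <- order(all$mz)
  idx <- seq_len(nrow(all))[o]
  mzs <- all$mz[o]
  gap <- diff(mzs)
  tol <- pmax(params@mzdiff, 2 * params@ppm * 1e-6 * mzs[-length(mzs)])
  sliceId <- cumsum(c(1L, as.integer(gap > tol)))
  groups <- list()
  for (sl in split(idx, sliceId)) {
    if (length(sl) == 1L) { groups[[length(groups) + 1L]] <- sl; next }
    rts <- all$rt[sl]
    if (max(rts) - min(rts) < 1e-9) { groups[[length(groups) + 1L]] <- sl; next }
    d <- stats::density(rts, bw = params@bw, n = 512,
                        from = min(rts) - 3 * params@bw,
                        to = max(rts) + 3 * params@bw)
    y <- d$y; nG <- length(y)
    isMin <- y < c(Inf, y[-nG]) & y <= c(y[-1], Inf)
    cuts <- d$x[isMin]
    bin <- findInterval(rts, sort(cuts))
    for (b in split(sl, bin)) groups[[length(groups) + 1L]] <- b
  }
  groups
}

#' Flag isotope-supported and low-intensity-isotope features
#'
#' A feature is a reliable peak (`hasIsotope`) when another feature sits
#' at `mz + 1.003355/z` (z = 1 or 2) within the ppm tolerance, co-elutes
#' within `rtTol` seconds, and has a mean-intensity ratio to the parent
#' in (0, `maxRatio`]. A reliable peak is additionally flagged
#' `lowIntensityIsotope` when its isotope's mean intensity falls below
#' the mean of the lowest 3% of all feature mean intensities.
#'
#' @param fs a [FeatureSet-class].
#' @param ppm m/z tolerance for the isotope spacing match.
#' @param rtTol maximum RT separation, seconds.
#' @param maxRatio maximum isotope/parent intensity ratio.
#' @param lowFraction quantile fraction defining the low-intensity floor.
#' @return the [FeatureSet-class] with `hasIsotope` and
#'   `lowIntensityIsotope` filled in.
#' @export
detectIsotopes <- function(fs, ppm = 20, rtTol = 3, maxRatio = 0.6,
                           lowFraction = 0.03) {
  stopifnot(is(fs, "FeatureSet"))
  ft <- fs@features
  n <- nrow(ft)
  if (n == 0L) return(fs)
  meanInt <- rowMeans(fs@intensities)
  nLow <- max(1L, ceiling(lowFraction * n))
  lowFloor <- mean(sort(meanInt)[seq_len(nLow)])
  hasIso <- logical(n); lowIso <- logical(n)
  DELTA <- 1.003355
  for (i in seq_len(n)) {
    for (z in c(1, 2)) {
      target <- ft$mz[i] + DELTA / z
      tol <- ppm * 1e-6 * target
      j <- which(abs(ft$mz - target) <= tol & abs(ft$rt - ft$rt[i]) <= rtTol)
      j <- j[j != i]
      if (!length(j)) next
      ratio <- meanInt[j] / meanInt[i]
      ok <- which(ratio > 0 & ratio <= maxRatio)
      if (length(ok)) {
        hasIso[i] <- TRUE
        if (any(meanInt[j[ok]] < lowFloor)) lowIso[i] <- TRUE
        break
      }
    }
  }
  ft$hasIsotope <- hasIso
  ft$lowIntensityIsotope <- lowIso
  initialize(fs, features = ft)
}
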