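# Region-of-interest selection and run trimming. The default "standards
# simulation method" (ssm) slides an intensity-summing window per m/z bin
# and a single shared window across the RT axis; the intersected boxes are
# the ROIs from which trimmed ("synthetic") spectra are assembled for
# parameter optimization.

#' Specify a trimming strategy
#'
#' @param strategy `"ssm"` (sliding-window ROI selection, the default),
#'   `"mz_specific"` or `"rt_specific"` (extract or remove targeted
#'   values).
#' @param nBins number of equal-width m/z bins (ssm); default 4.
#' @param mzWindowFraction sliding m/z window width as a fraction of each
#'   bin's width; default 0.25.
#' @param rtFraction RT window width as a fraction in (0, 1] of the run's
#'   RT span; default 0.25.
#' @param targets data.frame with columns `value`, `tol`, `unit` (one of
#'   `"ppm"`, `"da"`, `"s"`) for the targeted strategies.
#' @param keep TRUE extracts the targeted regions, FALSE removes them.
#' @return list of class `TrimSpec`.
#' @export
trimSpec <- function(strategy = c("ssm", "mz_specific", "rt_specific"),
                     nBins = 4L, mzWindowFraction = 0.25, rtFraction = 0.25,
                     targets = NULL, keep = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(nBins >= 1L, rtFraction > 0, rtFraction <= 1,
            mzWindowFraction > 0, mzWindowFraction <= 1)
  structure(list(strategy = strategy, nBins = as.integer(nBins),
                 mzWindowFraction = mzWindowFraction, rtFraction = rtFraction,
                 targets = targets, keep = keep),
            class = "TrimSpec")
}

# Pool all MS1 centroids of a run into one table.
poolPoints <- function(run) {
  ms1 <- which(vapply(run@scans, function(s) s$msLevel == 1L, logical(1)))
  n <- vapply(run@scans[ms1], function(s) length(s$mz), integer(1))
  data.frame(
    scan = rep(ms1, n),
    rt = rep(vapply(run@scans[ms1], `[[`, numeric(1), "rt"), n),
    mz = unlist(lapply(run@scans[ms1], `[[`, "mz"), use.names = FALSE),
    intensity = unlist(lapply(run@scans[ms1], `[[`, "intensity"), use.names = FALSE))
}

# Max-sum sliding window over 1-D points: windows of width `width` with
# left edges on the lattice seq(lo, hi - width, by = width/10); ties break
# toward the lower edge. Returns c(lo, hi, score).
slideMaxWindow <- function(x, w, lo, hi, width) {
  if (width <= 0 || hi - lo < width) return(NULL)
  starts <- seq(lo, hi - width, by = width / 10)
  o <- order(x)
  xs <- x[o]; ws <- w[o]
  cw <- c(0, cumsum(ws))
  iLo <- findInterval(starts, xs, left.open = TRUE) + 1L  # first index >= start
  iHi <- findInterval(starts + width, xs)                 # last index <= start+width
  sums <- cw[iHi + 1L] - cw[iLo]
  best <- which.max(sums)  # first maximum = lowest edge on ties
  c(starts[best], starts[best] + width, sums[best])
}

#' Select regions of interest enriched for real peaks
#'
#' Implements the ssm strategy: the m/z range is divided into `nBins`
#' equal bins; within each bin a window of `mzWindowFraction` of the bin
#' width slides (step = width/10) and the position with the highest summed
#' centroid intensity is retained. A single RT window of `rtFraction` of
#' the RT span slides across the whole run the same way. Each bin's best
#' m/z window intersected with the one best RT window gives one ROI.
#'
#' @param run a non-empty [SpectraRun-class].
#' @param spec a [trimSpec()] with `strategy = "ssm"`.
#' @return data.frame with one ROI per bin: `mzLo`, `mzHi`, `rtLo`,
#'   `rtHi`, `score` (summed intensity inside the box).
#' @export
selectROIs <- function(run, spec = trimSpec()) {
  stopifnot(is(run, "SpectraRun"), inherits(spec, "TrimSpec"))
  if (spec$strategy != "ssm") stop("selectROIs applies to the ssm strategy")
  pts <- poolPoints(run)
  if (nrow(pts) == 0L) stop("empty run: no centroids to select ROIs from")
  rtLo <- min(pts$rt); rtHi <- max(pts$rt)
  rtSpan <- rtHi - rtLo
  rtWidth <- spec$rtFraction * rtSpan
  if (rtSpan <= 0 || rtWidth <= 0)
    stop("run RT span too short for the requested RT window; increase rtFraction")
  rtWin <- slideMaxWindow(pts$rt, pts$intensity, rtLo, rtHi, rtWidth)
  if (is.null(rtWin))
    stop("run shorter than the RT window; increase rtFraction")
  mzLo <- min(pts$mz); mzHi <- max(pts$mz)
  binW <- (mzHi - mzLo) / spec$nBins
  if (binW <= 0) stop("degenerate m/z range")
  rois <- vector("list", spec$nBins)
  for (b in seq_len(spec$nBins)) {
    bLo <- mzLo + (b - 1) * binW
    bHi <- bLo + binW
    inBin <- pts$mz >= bLo & pts$mz <= bHi
    w <- spec$mzWindowFraction * binW
    win <- slideMaxWindow(pts$mz[inBin], pts$intensity[inBin], bLo, bHi, w)
    if (is.null(win)) win <- c(bLo, bLo + w, 0)
    inside <- pts$mz >= win[1] & pts$mz <= win[2] &
      pts$rt >= rtWin[1] & pts$rt <= rtWin[2]
    rois[[b]] <- data.frame(mzLo = win[1], mzHi = win[2],
                            rtLo = rtWin[1], rtHi = rtWin[2],
                            score = sum(pts$intensity[inside]))
  }
  do.call(rbind, rois)
}

#' Trim a run to (or around) regions of interest
#'
#' For the ssm strategy, keeps only the centroids inside the union of the
#' supplied ROI boxes (the trimmed run is the "synthetic spectra" the
#' optimizer works on). For `mz_specific` / `rt_specific`, the targeted
#' values with their tolerances define the regions, which are either
#' extracted (`keep = TRUE`) or removed (`keep = FALSE`). Scan retention
#' times are preserved; scans left empty are dropped.
#'
#' @param run a non-empty [SpectraRun-class].
#' @param spec a [trimSpec()].
#' @param rois data.frame from [selectROIs()] (ssm only; computed on the
#'   fly when NULL).
#' @return the trimmed [SpectraRun-class].
#' @export
trimRun <- function(run, spec = trimSpec(), rois = NULL) {
  stopifnot(is(run, "SpectraRun"), inherits(spec, "TrimSpec"))
  if (spec$strategy == "ssm") {
    if (is.null(rois)) rois <- selectROIs(run, spec)
    boxes <- rois
    keep <- TRUE
  } else {
    if (is.null(spec$targets) || nrow(spec$targets) == 0L)
      stop("targeted trimming needs a non-empty targets table")
    tg <- spec$targets
    boxes <- do.call(rbind, lapply(seq_len(nrow(tg)), function(i) {
      v <- tg$value[i]; tol <- tg$tol[i]; unit <- tg$unit[i]
      if (spec$strategy == "mz_specific") {
        half <- if (unit == "ppm") v * tol * 1e-6 else tol
        data.frame(mzLo = v - half, mzHi = v + half, rtLo = -Inf, rtHi = Inf)
      } else {
        data.frame(mzLo = -Inf, mzHi = Inf, rtLo = v - tol, rtHi = v + tol)
      }
    }))
    keep <- spec$keep
  }
  newScans <- list()
  for (s in run@scans) {
    if (s$msLevel != 1L) next
    if (length(s$mz) == 0L) next
    inside <- rep(FALSE, length(s$mz))
    for (b in seq_len(nrow(boxes))) {
      if (s$rt < boxes$rtLo[b] || s$rt > boxes$rtHi[b]) next
      inside <- inside | (s$mz >= boxes$mzLo[b] & s$mz <= boxes$mzHi[b])
    }
    sel <- if (keep) inside else !inside
    if (!any(sel)) next
    newScans[[length(newScans) + 1L]] <-
      list(rt = s$rt, mz = s$mz[sel], intensity = s$intensity[sel],
           msLevel = s$msLevel, polarity = s$polarity)
  }
  if (!length(newScans))
    stop("trimming removed every point: empty run")
  meta <- run@meta
  meta$trimmed <- spec$strategy
  SpectraRun(newScans, sampleId = run@sampleId, meta = meta)
}
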