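# Shared fixtures and independent oracles used across test files.

# A small three-peak run with isotopes and mild noise.
threePeakRun <- function(seed = 7, noise = list(baseline = 30, sd = 10, spikeRate = 40)) {
  pk <- plantedPeaks(mz = c(200.1, 350.2, 500.3), rtApex = c(60, 150, 240),
                     rtSigma = 4, height = c(2e4, 5e4, 1e4),
                     isotopePartner = c(TRUE, TRUE, FALSE),
                     isotopeAbundance = 0.2)
  simulateRun(pk, noise = noise, rtGrid = c(0, 300, 1), mzJitterPpm = 3,
              seed = seed)
}

permissiveParams <- function() {
  PickerParams(ppm = 20, peakwidthMin = 5, peakwidthMax = 40, mzdiff = 0.01,
               snthresh = 3, noise = 100, prefilterK = 3, prefilterI = 100,
               bw = 3)
}

# Brute-force sliding-window ROI search on the same position lattice the
# implementation uses (window step = width/10), summing naively per
# position; first maximum wins.
bruteForceRois <- function(run, spec) {
  pts <- metaboflow:::poolPoints(run)
  naiveBest <- function(x, w, lo, hi, width) {
    starts <- seq(lo, hi - width, by = width / 10)
    sums <- vapply(starts, function(s) sum(w[x >= s & x <= s + width]), numeric(1))
    i <- which.max(sums)
    c(starts[i], starts[i] + width, sums[i])
  }
  rtLo <- min(pts$rt); rtHi <- max(pts$rt)
  rtW <- spec$rtFraction * (rtHi - rtLo)
  rtWin <- naiveBest(pts$rt, pts$intensity, rtLo, rtHi, rtW)
  mzLo <- min(pts$mz); mzHi <- max(pts$mz)
  binW <- (mzHi - mzLo) / spec$nBins
  out <- list()
  for (b in seq_len(spec$nBins)) {
    bLo <- mzLo + (b - 1) * binW; bHi <- bLo + binW
    inBin <- pts$mz >= bLo & pts$mz <= bHi
    w <- spec$mzWindowFraction * binW
    win <- naiveBest(pts$mz[inBin], pts$intensity[inBin], bLo, bHi, w)
    inside <- pts$mz >= win[1] & pts$mz <= win[2] &
      pts$rt >= rtWin[1] & pts$rt <= rtWin[2]
    out[[b]] <- data.frame(mzLo = win[1], mzHi = win[2],
                           rtLo = rtWin[1], rtHi = rtWin[2],
                           score = sum(pts$intensity[inside]))
  }
  do.call(rbind, out)
}

# Construct a FeatureSet directly from per-feature specifications (used
# by the quality-score and acceptance tests).
makeFeatureSet <- function(n, nIso = 0, nLip = 0, nGauss = n, rcs = 1, gs = 4,
                           intensities = NULL) {
  ft <- data.frame(mz = 100 + 3 * seq_len(n), rt = rep(100, n),
                   gaussCor = c(rep(0.95, nGauss), rep(0.2, n - nGauss)),
                   gaussP = c(rep(0.001, nGauss), rep(0.5, n - nGauss)),
                   hasIsotope = c(rep(TRUE, nIso), rep(FALSE, n - nIso)),
                   lowIntensityIsotope = c(rep(TRUE, nLip), rep(FALSE, n - nLip)))
  if (is.null(intensities)) intensities <- matrix(1000, n, 2)
  FeatureSet(ft, intensities = intensities, rcs = rcs, gs = gs, nSamples = ncol(intensities))
}

# Exhaustive (feature x compound x form) m/z match oracle.
bruteForceMatch <- function(features, compounds, params) {
  forms <- ionForms(params$mode)
  rows <- list()
  for (i in seq_len(nrow(features)))
    for (j in seq_len(nrow(compounds)))
      for (k in seq_len(nrow(forms))) {
        theo <- (forms$multiplier[k] * compounds$mass[j] + forms$massShift[k]) /
          abs(forms$charge[k])
        if (abs(features$mz[i] - theo) / theo <= params$ppm * 1e-6)
          rows[[length(rows) + 1L]] <- data.frame(
            feature = i, compound = compounds$id[j], form = forms$name[k],
            stringsAsFactors = FALSE)
      }
  if (!length(rows)) return(data.frame(feature = integer(), compound = character(),
                                       form = character()))
  do.call(rbind, rows)
}
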