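# Ground-truthed simulators: raw runs, dilution series, batched feature
# tables and pathway libraries. Every generator is a pure function of its
# arguments and the seed, and returns its ground truth alongside the data.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specify peaks to plant in a synthetic run
#'
#' @param mz m/z of the monoisotopic ion, Th.
#' @param rtApex apex retention time, seconds.
#' @param rtSigma Gaussian chromatographic width (sigma), seconds.
#' @param height apex intensity, counts.
#' @param isotopePartner logical; if TRUE a +1.003355/charge Th trace is
#'   co-planted at `isotopeAbundance` relative height.
#' @param isotopeAbundance relative abundance of the isotope trace; NA
#'   draws uniformly from 0.05-0.3 at simulation time.
#' @param charge charge state (spaces the isotope at 1.003355/z).
#' @return data.frame of planted-peak rows.
#' @export
plantedPeaks <- function(mz, rtApex, rtSigma = 4, height = 1e4,
                         isotopePartner = FALSE, isotopeAbundance = NA_real_,
                         charge = 1L) {
  n <- length(mz)
  stopifnot(length(rtApex) == n)
  data.frame(mz = mz, rtApex = rtApex,
             rtSigma = rep_len(rtSigma, n), height = rep_len(height, n),
             isotopePartner = rep_len(isotopePartner, n),
             isotopeAbundance = rep_len(isotopeAbundance, n),
             charge = as.integer(rep_len(charge, n)))
}

#' Simulate a centroided LC-HRMS run with known ground truth
#'
#' Each planted peak contributes a Gaussian-in-time intensity profile
#' `height * exp(-(t - rtApex)^2 / (2 rtSigma^2))` sampled on the scan
#' grid; its centroid m/z is jittered per scan by `N(0, mzJitterPpm)`.
#' Isotope partners are co-planted at `mz + 1.003355/charge`. Noise points
#' are Poisson-many per scan, uniform in m/z over the simulated range,
#' with intensity `baseline + |N(0, sd)|`.
#'
#' @param peaks data.frame from [plantedPeaks()] (may have 0 rows).
#' @param noise list with `baseline`, `sd`, `spikeRate` (expected noise
#'   points per scan); all zero for a noiseless run.
#' @param rtGrid numeric `c(start, end, step)` in seconds.
#' @param mzJitterPpm per-scan m/z jitter (ppm standard deviation).
#' @param seed integer seed; the run is reproducible under a fixed seed.
#' @param sampleId label for the run.
#' @return A [SpectraRun-class]; its metadata carries `truth` (the planted
#'   peak table including materialized isotope rows and per-peak areas)
#'   and `perScanTIC` (the generator's per-scan intensity totals).
#' @export
simulateRun <- function(peaks = plantedPeaks(numeric(), numeric()),
                        noise = list(baseline = 0, sd = 0, spikeRate = 0),
                        rtGrid = c(0, 300, 1), mzJitterPpm = 0, seed = 1,
                        sampleId = "sim") {
  stopifnot(length(rtGrid) == 3, rtGrid[2] > rtGrid[1], rtGrid[3] > 0)
  if (nrow(peaks) && anyDuplicated(peaks[, c("mz", "rtApex")]))
    stop("overlapping identical (mz, rtApex) plants: ambiguous ground truth")
  withSeed(seed, {
    rts <- seq(rtGrid[1], rtGrid[2], by = rtGrid[3])
    # materialize isotope rows
    truth <- peaks
    truth$isIsotope <- rep(FALSE, nrow(truth))
    truth$parent <- rep(NA_integer_, nrow(truth))
    if (nrow(peaks)) {
      for (i in seq_len(nrow(peaks))) {
        if (isTRUE(peaks$isotopePartner[i])) {
          ab <- peaks$isotopeAbundance[i]
          if (is.na(ab)) ab <- stats::runif(1, 0.05, 0.3)
          iso <- peaks[i, ]
          iso$mz <- iso$mz + 1.003355 / max(1L, iso$charge)
          iso$height <- iso$height * ab
          iso$isotopePartner <- FALSE
          iso$isotopeAbundance <- ab
          iso$isIsotope <- TRUE
          iso$parent <- i
          truth <- rbind(truth, iso)
        }
      }
    }
    mzRange <- if (nrow(truth)) range(truth$mz) + c(-5, 5) else c(100, 1000)
    scansList <- vector("list", length(rts))
    tic <- numeric(length(rts))
    for (k in seq_along(rts)) {
      t <- rts[k]
      mzv <- numeric(0); iv <- numeric(0)
      if (nrow(truth)) {
        contrib <- truth$height * exp(-(t - truth$rtApex)^2 / (2 * truth$rtSigma^2))
        on <- contrib > pmax(1e-6 * truth$height, 1e-3)
        if (any(on)) {
          m <- truth$mz[on]
          if (mzJitterPpm > 0)
            m <- m * (1 + stats::rnorm(sum(on), 0, mzJitterPpm * 1e-6))
          mzv <- m; iv <- contrib[on]
        }
      }
      if (noise$spikeRate > 0 || noise$baseline > 0) {
        nn <- stats::rpois(1, noise$spikeRate)
        if (nn > 0) {
          nm <- stats::runif(nn, mzRange[1], mzRange[2])
          ni <- noise$baseline + abs(stats::rnorm(nn, 0, noise$sd))
          mzv <- c(mzv, nm); iv <- c(iv, ni)
        }
      }
      o <- order(mzv)
      mzv <- mzv[o]; iv <- iv[o]
      dup <- c(FALSE, diff(mzv) <= 0)
      if (any(dup)) { mzv <- mzv[!dup]; iv <- iv[!dup] }
      tic[k] <- sum(iv)
      scansList[[k]] <- list(rt = t, mz = mzv, intensity = iv,
                             msLevel = 1L, polarity = "unknown")
    }
    truth$area <- if (nrow(truth)) truth$height * truth$rtSigma * sqrt(2 * pi)
                  else numeric(0)
    SpectraRun(scansList, sampleId = sampleId,
               meta = list(truth = truth, perScanTIC = tic, seed = seed))
  })
}

#' Simulate a dilution series
#'
#' Produces one run per (factor, replicate): planted peak heights scale
#' linearly with the dilution factor while the noise model does not.
#'
#' @param peaks planted peak table (see [plantedPeaks()]).
#' @param factors positive dilution factors, e.g. `c(1, 0.2, 0.1, 0.05,
#'   0.025)` for a serum dilution series.
#' @param replicates runs per factor.
#' @inheritParams simulateRun
#' @return list of [SpectraRun-class]; each run's metadata records its
#'   `dilutionFactor` and `replicate`.
#' @export
simulateDilutionSeries <- function(peaks, factors, replicates = 1L,
                                   noise = list(baseline = 0, sd = 0, spikeRate = 0),
                                   rtGrid = c(0, 300, 1), mzJitterPpm = 0,
                                   seed = 1) {
  if (length(factors) == 0L) stop("factors must be non-empty")
  if (any(factors <= 0)) stop("factors must be positive")
  runs <- list()
  idx <- 0L
  for (r in seq_len(replicates)) {
    for (f in factors) {
      idx <- idx + 1L
      pk <- peaks
      pk$height <- pk$height * f
      run <- simulateRun(pk, noise = noise, rtGrid = rtGrid,
                         mzJitterPpm = mzJitterPpm, seed = seed + idx,
                         sampleId = sprintf("dil_f%g_r%d", f, r))
      run@meta$dilutionFactor <- f
      run@meta$replicate <- r
      runs[[idx]] <- run
    }
  }
  runs
}

#' Simulate a batch-affected feature intensity table
#'
#' Generates a features x samples matrix with known clean signal plus
#' configurable batch effects: per-batch multiplicative/additive shifts,
#' a monotone multiplicative injection-order drift, and periodic pooled-QC
#' injections (the mean of all clean biological profiles plus noise).
#'
#' @param nFeatures,nSamples table dimensions (samples = biological
#'   injections; QCs are added on top every `qcEvery` injections).
#' @param nBatches number of batches (samples split contiguously in
#'   injection order).
#' @param batchShift numeric vector, one multiplicative factor per batch
#'   (recycled); 1 means no shift. Batch effects in LC-MS are
#'   feature-specific (response factors drift differently per compound),
#'   so a shifted batch multiplies feature f by
#'   `exp(log(shift) + N(0, batchFeatureSd))`; a shift of exactly 1
#'   applies no effect at all.
#' @param batchFeatureSd log-scale spread of the per-feature batch
#'   effect around its batch mean (default 0.15).
#' @param batchAdd additive per-batch offset on the log scale (recycled).
#' @param drift multiplicative drift slope per injection: sample at
#'   injection order i has feature f scaled by `1 + drift_f * i`, where
#'   `drift_f = drift * U(0.5, 1.5)` per feature (signal drift is
#'   likewise compound-dependent); 0 disables drift.
#' @param qcEvery insert one pooled QC after every `qcEvery` biological
#'   samples (0 = no QCs).
#' @param groupEffect multiplicative fold-change applied to the first
#'   `nAffected` features in biological group "B".
#' @param nAffected number of group-affected features.
#' @param cv biological/technical coefficient of variation (log-normal).
#' @param seed integer seed.
#' @return list with `intensity` (features x samples, positive), `design`
#'   (a [BatchDesign-class]) and `clean` (the ground-truth matrix with no
#'   batch, drift or QC noise applied).
#' @export
simulateBatchedTable <- function(nFeatures = 200, nSamples = 40, nBatches = 2,
                                 batchShift = c(1, 2), batchFeatureSd = 0.15,
                                 batchAdd = 0, drift = 0, qcEvery = 0,
                                 groupEffect = 1, nAffected = 20, cv = 0.15,
                                 seed = 1) {
  stopifnot(nBatches >= 1, nFeatures >= 2, nSamples >= nBatches)
  withSeed(seed, {
    baseMean <- stats::runif(nFeatures, 8, 14)  # log-scale feature means
    groupsBio <- rep(c("A", "B"), length.out = nSamples)
    nAffected <- min(nAffected, nFeatures)
    # clean biological signal
    logClean <- matrix(stats::rnorm(nFeatures * nSamples, 0, cv),
                       nFeatures, nSamples) + baseMean
    if (groupEffect != 1 && nAffected > 0) {
      bIdx <- which(groupsBio == "B")
      logClean[seq_len(nAffected), bIdx] <-
        logClean[seq_len(nAffected), bIdx] + log(groupEffect)
    }
    clean <- exp(logClean)
    meanProfile <- rowMeans(clean)
    # interleave QCs
    ids <- character(); grp <- character(); qc <- logical(); src <- integer()
    bioCount <- 0L
    for (i in seq_len(nSamples)) {
      bioCount <- bioCount + 1L
      ids <- c(ids, sprintf("S%03d", i)); grp <- c(grp, groupsBio[i])
      qc <- c(qc, FALSE); src <- c(src, i)
      if (qcEvery > 0 && bioCount %% qcEvery == 0L) {
        ids <- c(ids, sprintf("QC%03d", length(ids) + 1L))
        grp <- c(grp, "QC"); qc <- c(qc, TRUE); src <- c(src, NA_integer_)
      }
    }
    nTot <- length(ids)
    batch <- rep(seq_len(nBatches), each = ceiling(nTot / nBatches))[seq_len(nTot)]
    shift <- rep_len(batchShift, nBatches)
    add <- rep_len(batchAdd, nBatches)
    # per-feature batch multipliers: identity for unshifted batches
    batchFac <- matrix(1, nFeatures, nBatches)
    for (b in seq_len(nBatches)) {
      if (shift[b] != 1 || add[b] != 0)
        batchFac[, b] <- exp(log(shift[b]) + add[b] +
                             stats::rnorm(nFeatures, 0, batchFeatureSd))
    }
    driftF <- if (drift != 0) drift * stats::runif(nFeatures, 0.5, 1.5) else rep(0, nFeatures)
    mat <- matrix(0, nFeatures, nTot, dimnames = list(
      sprintf("F%04d", seq_len(nFeatures)), ids))
    cleanOut <- mat
    for (j in seq_len(nTot)) {
      base <- if (qc[j]) {
        meanProfile * exp(stats::rnorm(nFeatures, 0, cv / 2))
      } else clean[, src[j]]
      cleanOut[, j] <- base
      v <- base * batchFac[, batch[j]] * (1 + driftF * j)
      mat[, j] <- pmax(v, .Machine$double.eps)
    }
    design <- BatchDesign(ids, batch = paste0("b", batch), group = grp,
                          isQC = qc, injectionOrder = seq_len(nTot))
    list(intensity = mat, design = design, clean = cleanOut)
  })
}

#' Simulate an m/z feature table and pathway library with a planted signal
#'
#' Builds a compound universe with random monoisotopic masses, a pathway
#' library over it (one designated pathway can be enriched), and an
#' LC-HRMS-like feature list: each compound emits 1-4 ion-form features
#' (the primary ion is present with probability `pPrimary`) at
#' form-consistent m/z, co-eluting within a shared retention-time window.
#' With `effect > 0` that fraction of the enriched pathway's compounds has
#' all its features made significant.
#'
#' @param nCompounds size of the compound universe. The default (120
#'   compounds over 15 pathways) is a scaled-down image of real
#'   metabolic pathway libraries (dozens of pathways over hundreds to
#'   thousands of compounds); much smaller toys make the hypergeometric
#'   null too discrete for meaningful permutation calibration.
#' @param nPathways number of pathways (the first is the enriched one).
#' @param enrichedPathwaySize compounds in the enriched pathway.
#' @param mode ionization mode, `"positive"` or `"negative"`.
#' @param effect fraction in [0,1] of the enriched pathway's compounds
#'   whose features are made significant; 0 gives a null dataset.
#' @param pPrimary probability that a compound's primary ion is observed.
#' @param maxRt chromatographic run length, seconds.
#' @param sigP significant features draw p ~ U(0, sigP).
#' @param seed integer seed.
#' @return list with `features` (data.frame `mz`, `rt`, `p`, `statistic`),
#'   `library` (named list pathway -> compound ids), `compounds`
#'   (data.frame `id`, `mass`) and `truth` (enriched pathway name and the
#'   significant compound ids).
#' @export
simulatePathwayData <- function(nCompounds = 120, nPathways = 15,
                                enrichedPathwaySize = 15,
                                mode = c("positive", "negative"),
                                effect = 0, pPrimary = 0.9, maxRt = 600,
                                sigP = 1e-4, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(enrichedPathwaySize <= nCompounds)
  withSeed(seed, {
    cmpd <- data.frame(id = sprintf("C%04d", seq_len(nCompounds)),
                       mass = stats::runif(nCompounds, 100, 800),
                       stringsAsFactors = FALSE)
    lib <- list()
    lib[["pathway_01"]] <- cmpd$id[seq_len(enrichedPathwaySize)]
    for (p in seq_len(nPathways - 1L)) {
      sz <- sample(5:15, 1)
      lib[[sprintf("pathway_%02d", p + 1L)]] <- sample(cmpd$id, min(sz, nCompounds))
    }
    forms <- ionForms(mode)
    prim <- forms[forms$isPrimary, , drop = FALSE]
    primMain <- prim[1, ]  # M+H / M-H
    sigCmpd <- character()
    if (effect > 0) {
      k <- round(effect * enrichedPathwaySize)
      sigCmpd <- lib[["pathway_01"]][seq_len(k)]
    }
    rows <- list()
    for (i in seq_len(nCompounds)) {
      rtC <- stats::runif(1, 30, maxRt - 30)
      nForms <- sample(1:4, 1)
      emitted <- list()
      if (stats::runif(1) < pPrimary) emitted[[1]] <- primMain
      extra <- forms[sample(nrow(forms), min(nForms, nrow(forms))), , drop = FALSE]
      for (r in seq_len(nrow(extra))) emitted[[length(emitted) + 1L]] <- extra[r, ]
      if (!length(emitted)) next
      emitted <- unique(do.call(rbind, emitted))
      isSig <- cmpd$id[i] %in% sigCmpd
      for (r in seq_len(nrow(emitted))) {
        f <- emitted[r, ]
        mzTheo <- (f$multiplier * cmpd$mass[i] + f$massShift) / abs(f$charge)
        rows[[length(rows) + 1L]] <- data.frame(
          mz = mzTheo * (1 + stats::rnorm(1, 0, 2e-6)),
          rt = rtC + stats::runif(1, -2, 2),
          p = if (isSig) stats::runif(1, 0, sigP) else stats::runif(1),
          compound = cmpd$id[i], form = f$name, stringsAsFactors = FALSE)
      }
    }
    feat <- do.call(rbind, rows)
    feat$statistic <- stats::qnorm(1 - feat$p / 2)
    rownames(feat) <- NULL
    list(features = feat[, c("mz", "rt", "p", "statistic", "compound", "form")],
         library = lib, compounds = cmpd,
         truth = list(enriched = "pathway_01", sigCompounds = sigCmpd))
  })
}
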