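# Raw-run I/O: mzML / mzXML via mzR, plus whole-run inspection.

#' Read a centroided LC-HRMS run
#'
#' Reads an mzML or mzXML file (dialect auto-detected from the extension,
#' falling back to the root XML element) and returns the scans at the
#' requested MS level as a [SpectraRun-class]. Retention times are stored
#' in seconds. Profile-mode scans are reduced to centroids by local-maximum
#' reduction and the run is flagged with `centroided_from_profile` in its
#' metadata.
#'
#' @param path path to an mzML or mzXML file.
#' @param msLevel MS level to retain (default 1; higher levels are ignored
#'   downstream).
#' @return A [SpectraRun-class].
#' @export
readSpectra <- function(path, msLevel = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  detectDialect(path)  # errors early on non-MS XML
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e)))
  on.exit(try(mzR::close(ms), silent = TRUE), add = TRUE)
  hdr <- mzR::header(ms)
  if (nrow(hdr) == 0L) stop("empty run: no scans in ", path)
  keep <- which(hdr$msLevel == msLevel)
  if (msLevel == 1L && length(keep) == 0L) stop("empty run: no MS1 scans in ", path)
  if (length(keep) == 0L) stop("no scans at msLevel ", msLevel, " in ", path)

  fromProfile <- FALSE
  scanList <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    pk <- tryCatch(mzR::peaks(ms, i),
                   error = function(e) stop("corrupt scan ", i, " in ", path, ": ",
                                            conditionMessage(e)))
    mz <- pk[, 1]; inten <- pk[, 2]
    centroided <- hdr$centroided[i]
    if (!is.na(centroided) && !centroided && length(mz) > 2L) {
      red <- centroidProfile(mz, inten)
      mz <- red$mz; inten <- red$intensity
      fromProfile <- TRUE
    }
    o <- order(mz)
    mz <- mz[o]; inten <- inten[o]
    dup <- c(FALSE, diff(mz) <= 0)
    if (any(dup)) { mz <- mz[!dup]; inten <- inten[!dup] }
    pol <- if (is.null(hdr$polarity)) NA_integer_ else hdr$polarity[i]
    scanList[[j]] <- list(
      rt = hdr$retentionTime[i], mz = mz, intensity = inten,
      msLevel = as.integer(hdr$msLevel[i]),
      polarity = if (is.na(pol) || pol < 0) "unknown" else if (pol == 1) "positive" else "negative")
  }
  o <- order(vapply(scanList, `[[`, numeric(1), "rt"))
  meta <- list(source = path)
  if (fromProfile) meta$centroided_from_profile <- TRUE
  SpectraRun(scanList[o],
             sampleId = tools::file_path_sans_ext(basename(path)),
             meta = meta)
}

# Extension first, then root element: <mzML|indexedmzML> vs <mzXML>.
detectDialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mzml", "mzxml")) return(ext)
  head <- readChar(path, nchars = 2000L, useBytes = TRUE)
  if (grepl("<(indexedmzML|mzML)[ >]", head)) return("mzml")
  if (grepl("<mzXML[ >]", head)) return("mzxml")
  stop("not a recognizable mzML/mzXML file: ", path)
}

# Local-maximum reduction of a profile scan: one centroid per local apex,
# intensity-weighted m/z over the apex and its immediate neighbours.
centroidProfile <- function(mz, inten) {
  n <- length(inten)
  apex <- which(inten > c(-Inf, inten[-n]) & inten >= c(inten[-1], -Inf) & inten > 0)
  if (!length(apex)) return(list(mz = numeric(), intensity = numeric()))
  cm <- vapply(apex, function(i) {
    idx <- max(1L, i - 1L):min(n, i + 1L)
    sum(mz[idx] * inten[idx]) / sum(inten[idx])
  }, numeric(1))
  list(mz = cm, intensity = inten[apex])
}

#' Write a run to mzML
#'
#' Writes a [SpectraRun-class] as standard mzML (64-bit m/z and intensity
#' arrays) so that trimmed or synthetic runs can be fed to any external
#' peak picker. `readSpectra(writeSpectra(run))` is an identity up to
#' float64 round-off.
#'
#' @param run a non-empty [SpectraRun-class].
#' @param path output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(run, path) {
  stopifnot(is(run, "SpectraRun"))
  if (length(run) == 0L) stop("cannot write an empty run")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", path)
  n <- length(run@scans)
  polcode <- function(p) switch(p, positive = 1L, negative = 0L, -1L)
  pks <- lapply(run@scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(run@scans, function(s) as.integer(s$msLevel), integer(1)),
    polarity = vapply(run@scans, function(s) polcode(s$polarity), integer(1)),
    peaksCount = vapply(run@scans, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(run@scans, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(run@scans, function(s) s$rt, numeric(1)),
    basePeakMZ = vapply(run@scans, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run@scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run@scans, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run@scans, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE)
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Summarize a run
#'
#' Whole-run inspection: scan count, retention-time and m/z extrema, and
#' the total ion chromatogram (per-MS1-scan summed intensity).
#'
#' @param run a non-empty [SpectraRun-class].
#' @return list with `nScans`, `rtRange`, `mzRange`, and `tic`
#'   (data.frame `rt`, `intensity`, one row per MS1 scan).
#' @export
inspectRun <- function(run) {
  stopifnot(is(run, "SpectraRun"))
  if (length(run) == 0L) stop("empty run")
  ms1 <- Filter(function(s) s$msLevel == 1L, run@scans)
  rts <- vapply(ms1, `[[`, numeric(1), "rt")
  tic <- vapply(ms1, function(s) sum(s$intensity), numeric(1))
  allmz <- unlist(lapply(ms1, `[[`, "mz"), use.names = FALSE)
  list(nScans = length(run@scans),
       rtRange = range(scanTimes(run)),
       mzRange = if (length(allmz)) range(allmz) else c(NA_real_, NA_real_),
       tic = data.frame(rt = rts, intensity = tic))
}
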