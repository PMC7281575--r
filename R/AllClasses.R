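#' @import methods
NULL

#' Container for a centroided LC-HRMS run
#'
#' A `SpectraRun` holds the ordered scans of one acquisition: per scan a
#' retention time (seconds), an ascending m/z vector (Thomson) and a
#' matching non-negative intensity vector, plus MS level and polarity.
#' Scans are stored as plain lists so that synthetic, trimmed and
#' file-derived runs share one representation.
#'
#' @slot scans list of scans; each scan is a list with elements `rt`
#'   (seconds), `mz` (numeric, strictly ascending), `intensity` (numeric,
#'   same length), `msLevel` (integer >= 1), `polarity` (one of
#'   `"positive"`, `"negative"`, `"unknown"`).
#' @slot sampleId single character label.
#' @slot meta named list of free-form metadata (group, batch, injection
#'   order, provenance flags such as `centroided_from_profile`).
#'
#' @export
setClass("SpectraRun",
  representation(scans = "list", sampleId = "character", meta = "list"),
  prototype(scans = list(), sampleId = "run", meta = list())
)

setValidity("SpectraRun", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L) msgs <- c(msgs, "sampleId must be a single string")
  rts <- vapply(object@scans, function(s) as.numeric(s$rt), numeric(1))
  if (length(rts) && any(rts < 0)) msgs <- c(msgs, "scan rt must be >= 0")
  if (length(rts) > 1L && any(diff(rts) < 0)) msgs <- c(msgs, "scan rts must be non-decreasing")
  for (i in seq_along(object@scans)) {
    s <- object@scans[[i]]
    if (length(s$mz) != length(s$intensity)) {
      msgs <- c(msgs, sprintf("scan %d: mz and intensity lengths differ", i)); break
    }
    if (length(s$mz) > 1L && any(diff(s$mz) <= 0)) {
      msgs <- c(msgs, sprintf("scan %d: mz not strictly ascending", i)); break
    }
    if (length(s$intensity) && any(s$intensity < 0)) {
      msgs <- c(msgs, sprintf("scan %d: negative intensity", i)); break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectraRun
#'
#' @param scans list of scans (see [SpectraRun-class]).
#' @param sampleId sample label.
#' @param meta named list of metadata.
#' @return A [SpectraRun-class] object.
#' @export
SpectraRun <- function(scans = list(), sampleId = "run", meta = list()) {
  scans <- lapply(scans, function(s) {
    list(rt = as.numeric(s$rt), mz = as.numeric(s$mz),
         intensity = as.numeric(s$intensity),
         msLevel = if (is.null(s$msLevel)) 1L else as.integer(s$msLevel),
         polarity = if (is.null(s$polarity)) "unknown" else as.character(s$polarity))
  })
  new("SpectraRun", scans = scans, sampleId = sampleId, meta = meta)
}

#' @describeIn SpectraRun Number of scans in the run.
#' @param x,object a `SpectraRun`.
#' @export
setMethod("length", "SpectraRun", function(x) length(x@scans))

#' Accessors for SpectraRun
#'
#' `scans()` returns the scan list, `sampleId()` the label, `runMeta()`
#' the metadata list, `scanTimes()` the vector of scan retention times.
#'
#' @param object a [SpectraRun-class].
#' @return See individual descriptions.
#' @export
setGeneric("scans", function(object) standardGeneric("scans"))

#' @rdname scans
#' @export
setMethod("scans", "SpectraRun", function(object) object@scans)

#' @rdname scans
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname scans
#' @export
setMethod("sampleId", "SpectraRun", function(object) object@sampleId)

#' @rdname scans
#' @export
setGeneric("runMeta", function(object) standardGeneric("runMeta"))

#' @rdname scans
#' @export
setMethod("runMeta", "SpectraRun", function(object) object@meta)

#' @rdname scans
#' @export
setGeneric("scanTimes", function(object) standardGeneric("scanTimes"))

#' @rdname scans
#' @export
setMethod("scanTimes", "SpectraRun", function(object)
  vapply(object@scans, function(s) s$rt, numeric(1)))

setMethod("show", "SpectraRun", function(object) {
  n <- length(object@scans)
  cat("SpectraRun '", object@sampleId, "': ", n, " scan(s)", sep = "")
  if (n) {
    rts <- scanTimes(object)
    np <- sum(vapply(object@scans, function(s) length(s$mz), integer(1)))
    cat(sprintf(", rt %.1f-%.1f s, %d centroids", min(rts), max(rts), np))
  }
  cat("\n")
  invisible(object)
})

#' Peak-picking parameter vector
#'
#' The optimizable parameters of the centWave-style peak detector:
#' m/z chaining tolerance (`ppm`), chromatographic peak-width bounds in
#' seconds, minimum m/z separation of distinct peaks (`mzdiff`, Th),
#' signal-to-noise threshold, absolute noise floor (counts), prefilter
#' (at least `prefilterK` consecutive scans above `prefilterI` counts),
#' grouping kernel bandwidth `bw` (seconds) and the minimum fraction of
#' samples `minfrac` defining a well-behaved feature group.
#'
#' @slot ppm,peakwidthMin,peakwidthMax,mzdiff,snthresh,noise,prefilterK,prefilterI,bw,minfrac numeric scalars.
#' @export
setClass("PickerParams",
  representation(ppm = "numeric", peakwidthMin = "numeric", peakwidthMax = "numeric",
                 mzdiff = "numeric", snthresh = "numeric", noise = "numeric",
                 prefilterK = "numeric", prefilterI = "numeric",
                 bw = "numeric", minfrac = "numeric"))

setValidity("PickerParams", function(object) {
  msgs <- character()
  if (!(object@peakwidthMin < object@peakwidthMax))
    msgs <- c(msgs, "peakwidthMin must be < peakwidthMax")
  for (nm in c("ppm", "mzdiff", "bw"))
    if (slot(object, nm) <= 0) msgs <- c(msgs, paste(nm, "must be > 0"))
  if (object@snthresh < 0) msgs <- c(msgs, "snthresh must be >= 0")
  if (object@noise < 0) msgs <- c(msgs, "noise must be >= 0")
  if (object@prefilterK < 1) msgs <- c(msgs, "prefilterK must be >= 1")
  if (object@minfrac < 0 || object@minfrac > 1) msgs <- c(msgs, "minfrac in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PickerParams
#'
#' @param ppm m/z tolerance for trace chaining, parts per million.
#' @param peakwidthMin,peakwidthMax chromatographic peak width bounds, seconds.
#' @param mzdiff minimum m/z difference between distinct peaks, Th.
#' @param snthresh minimum signal-to-noise ratio.
#' @param noise absolute intensity floor, counts.
#' @param prefilterK,prefilterI prefilter: traces must have at least
#'   `prefilterK` consecutive points above `prefilterI` counts.
#' @param bw retention-time grouping bandwidth, seconds.
#' @param minfrac minimum fraction of samples for a well-behaved group.
#' @return A [PickerParams-class] object.
#' @export
PickerParams <- function(ppm = 30, peakwidthMin = 5, peakwidthMax = 30,
                         mzdiff = 0.01, snthresh = 6, noise = 100,
                         prefilterK = 3, prefilterI = 100, bw = 5,
                         minfrac = 0.5) {
  new("PickerParams", ppm = ppm, peakwidthMin = peakwidthMin,
      peakwidthMax = peakwidthMax, mzdiff = mzdiff, snthresh = snthresh,
      noise = noise, prefilterK = prefilterK, prefilterI = prefilterI,
      bw = bw, minfrac = minfrac)
}

#' Convert PickerParams to and from a named list
#' @param object a [PickerParams-class].
#' @return `paramsAsList()` a named list; `paramsFromList()` a
#'   [PickerParams-class].
#' @export
paramsAsList <- function(object) {
  stopifnot(is(object, "PickerParams"))
  nms <- slotNames(object)
  stats::setNames(lapply(nms, function(n) slot(object, n)), nms)
}

#' @rdname paramsAsList
#' @param x named list with PickerParams fields (missing fields take
#'   constructor defaults).
#' @export
paramsFromList <- function(x) do.call(PickerParams, x[names(x) %in% names(formals(PickerParams))])

setMethod("show", "PickerParams", function(object) {
  cat("PickerParams:\n")
  l <- paramsAsList(object)
  cat(paste0("  ", names(l), " = ", unlist(l), collapse = "\n"), "\n")
  invisible(object)
})

#' Grouped cross-sample feature set
#'
#' Result of grouping and aligning per-sample chromatographic peaks.
#' `features` has one row per feature (consensus `mz`, `rt`, per-feature
#' Gaussian shape statistics aggregated from members, isotope flags);
#' `intensities` is the features x samples area matrix; `rcs` and `gs`
#' are the retention-time correction score and the grouping score used
#' by the optimizer.
#'
#' @slot features data.frame with columns `mz`, `rt`, `gaussCor`,
#'   `gaussP`, `hasIsotope`, `lowIntensityIsotope`.
#' @slot intensities numeric matrix, features x samples.
#' @slot members list (one element per feature) of per-sample member
#'   peak rows.
#' @slot rcs,gs numeric scalars; alignment and grouping quality scores.
#' @slot nSamples integer.
#' @export
setClass("FeatureSet",
  representation(features = "data.frame", intensities = "matrix",
                 members = "list", rcs = "numeric", gs = "numeric",
                 nSamples = "integer"))

setValidity("FeatureSet", function(object) {
  msgs <- character()
  need <- c("mz", "rt", "gaussCor", "gaussP", "hasIsotope", "lowIntensityIsotope")
  if (!all(need %in% names(object@features)))
    msgs <- c(msgs, paste("features must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@features) != nrow(object@intensities))
    msgs <- c(msgs, "features and intensities row counts differ")
  if (!is.finite(object@rcs) || !is.finite(object@gs))
    msgs <- c(msgs, "rcs and gs must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureSet
#'
#' @param features data.frame of per-feature rows (see
#'   [FeatureSet-class]); missing score/flag columns are filled with
#'   neutral defaults.
#' @param intensities features x samples matrix (default: zero matrix,
#'   one column).
#' @param members per-feature member peak list.
#' @param rcs,gs alignment / grouping quality scores.
#' @param nSamples number of samples grouped.
#' @return A [FeatureSet-class] object.
#' @export
FeatureSet <- function(features, intensities = NULL, members = list(),
                       rcs = 1, gs = 0, nSamples = 1L) {
  features <- as.data.frame(features)
  if (is.null(features$gaussCor)) features$gaussCor <- NA_real_
  if (is.null(features$gaussP)) features$gaussP <- NA_real_
  if (is.null(features$hasIsotope)) features$hasIsotope <- FALSE
  if (is.null(features$lowIntensityIsotope)) features$lowIntensityIsotope <- FALSE
  if (is.null(intensities))
    intensities <- matrix(0, nrow = nrow(features), ncol = max(1L, nSamples))
  new("FeatureSet", features = features, intensities = intensities,
      members = members, rcs = as.numeric(rcs), gs = as.numeric(gs),
      nSamples = as.integer(nSamples))
}

#' Accessors for FeatureSet
#' @param object a [FeatureSet-class].
#' @return `featureTable()` the per-feature data.frame;
#'   `featureIntensities()` the features x samples matrix; `rcsScore()`
#'   and `gsScore()` the alignment / grouping scores.
#' @export
setGeneric("featureTable", function(object) standardGeneric("featureTable"))

#' @rdname featureTable
#' @export
setMethod("featureTable", "FeatureSet", function(object) object@features)

#' @rdname featureTable
#' @export
setGeneric("featureIntensities", function(object) standardGeneric("featureIntensities"))

#' @rdname featureTable
#' @export
setMethod("featureIntensities", "FeatureSet", function(object) object@intensities)

#' @rdname featureTable
#' @export
setGeneric("rcsScore", function(object) standardGeneric("rcsScore"))

#' @rdname featureTable
#' @export
setMethod("rcsScore", "FeatureSet", function(object) object@rcs)

#' @rdname featureTable
#' @export
setGeneric("gsScore", function(object) standardGeneric("gsScore"))

#' @rdname featureTable
#' @export
setMethod("gsScore", "FeatureSet", function(object) object@gs)

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d feature(s) x %d sample(s); RCS %.3g, GS %.3g\n",
              nrow(object@features), object@nSamples, object@rcs, object@gs))
  invisible(object)
})

#' Sample design for batch correction
#'
#' Maps each sample to its batch, biological group, QC status and
#' injection order. QC-dependent correctors require at least three QC
#' samples spanning the injection-order range.
#'
#' @slot sampleIds character.
#' @slot batch factor, one level per batch.
#' @slot group factor, biological class.
#' @slot isQC logical.
#' @slot injectionOrder integer, unique positive.
#' @export
setClass("BatchDesign",
  representation(sampleIds = "character", batch = "factor", group = "factor",
                 isQC = "logical", injectionOrder = "integer"))

setValidity("BatchDesign", function(object) {
  n <- length(object@sampleIds)
  msgs <- character()
  if (length(object@batch) != n || length(object@group) != n ||
      length(object@isQC) != n || length(object@injectionOrder) != n)
    msgs <- c(msgs, "all fields must have one entry per sample")
  if (n && nlevels(droplevels(object@batch)) < 1) msgs <- c(msgs, "at least one batch")
  if (anyDuplicated(object@injectionOrder)) msgs <- c(msgs, "injectionOrder must be unique")
  if (n && any(object@injectionOrder < 1)) msgs <- c(msgs, "injectionOrder must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BatchDesign
#'
#' @param sampleIds character vector of sample labels.
#' @param batch batch label per sample.
#' @param group biological group per sample.
#' @param isQC logical; TRUE for pooled QC injections.
#' @param injectionOrder unique positive integers.
#' @return A [BatchDesign-class] object.
#' @export
BatchDesign <- function(sampleIds, batch, group = rep("g", length(sampleIds)),
                        isQC = rep(FALSE, length(sampleIds)),
                        injectionOrder = seq_along(sampleIds)) {
  new("BatchDesign", sampleIds = as.character(sampleIds),
      batch = factor(batch), group = factor(group), isQC = as.logical(isQC),
      injectionOrder = as.integer(injectionOrder))
}

#' Accessors for BatchDesign
#' @param object a [BatchDesign-class].
#' @return the corresponding per-sample vector.
#' @export
setGeneric("batchOf", function(object) standardGeneric("batchOf"))

#' @rdname batchOf
#' @export
setMethod("batchOf", "BatchDesign", function(object) object@batch)

#' @rdname batchOf
#' @export
setGeneric("groupOf", function(object) standardGeneric("groupOf"))

#' @rdname batchOf
#' @export
setMethod("groupOf", "BatchDesign", function(object) object@group)

#' @rdname batchOf
#' @export
setGeneric("isQC", function(object) standardGeneric("isQC"))

#' @rdname batchOf
#' @export
setMethod("isQC", "BatchDesign", function(object) object@isQC)

#' @rdname batchOf
#' @export
setGeneric("injectionOrder", function(object) standardGeneric("injectionOrder"))

#' @rdname batchOf
#' @export
setMethod("injectionOrder", "BatchDesign", function(object) object@injectionOrder)

#' @rdname batchOf
#' @export
setMethod("length", "BatchDesign", function(x) length(x@sampleIds))

setMethod("show", "BatchDesign", function(object) {
  cat(sprintf("BatchDesign: %d sample(s), %d batch(es), %d group(s), %d QC\n",
              length(object@sampleIds), nlevels(droplevels(object@batch)),
              nlevels(droplevels(object@group)), sum(object@isQC)))
  invisible(object)
})

#' Convert a BatchDesign to a data.frame
#' @param design a [BatchDesign-class].
#' @return data.frame with columns sample_id, batch, group, is_qc,
#'   injection_order (the on-disk TSV layout).
#' @export
designAsFrame <- function(design) {
  data.frame(sample_id = design@sampleIds, batch = as.character(design@batch),
             group = as.character(design@group), is_qc = design@isQC,
             injection_order = design@injectionOrder, stringsAsFactors = FALSE)
}

#' @rdname designAsFrame
#' @param df data.frame in the layout written by [designAsFrame()].
#' @export
designFromFrame <- function(df) {
  BatchDesign(df$sample_id, df$batch, df$group, as.logical(df$is_qc),
              df$injection_order)
}
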