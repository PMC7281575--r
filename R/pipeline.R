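# End-to-end orchestration: trim -> optimize -> pick -> correct -> enrich
# over files, with a reproducibility manifest. Stages are toggled and
# parameterized by a single structured config (a named list, or a YAML
# file path); the global seed propagates to every stochastic stage.

#' Run the metabolomics pipeline
#'
#' Executes the enabled stages in order on file inputs, writing each
#' stage's outputs under `outDir` together with `manifest.json` (inputs,
#' parameters, seeds, output checksums, wall-clock seconds per stage).
#' Identical config + seed produce identical checksums for the
#' deterministic stages. A stage whose upstream artifact is missing
#' aborts with a configuration error naming the gap.
#'
#' Config layout (all stages optional):
#' \preformatted{
#' seed: 1
#' outDir: out/
#' input:
#'   mzml: [a.mzML, b.mzML]     # raw runs (trim/optimize/pick)
#'   table: feats.tsv           # features x samples TSV (correct)
#'   design: design.tsv         # sample_id/batch/group/is_qc/injection_order
#'   peaklist: peaks.tsv        # mz/rt/p TSV (enrich)
#'   librar: library.json       # pathway -> compound ids + masses (enrich)
#' stages:
#'   trim:     {enabled: true, rtFraction: 0.25, nBins: 4}
#'   optimize: {enabled: true, platform: generic, maxRounds: 3}
#'   pick:     {enabled: true}
#'   correct:  {enabled: true, candidates: [eigenms, combat, qc_rlsc, none]}
#'   enrich:   {enabled: true, mode: positive, ppm: 10, pCutoff: 0.05}
#' }
#'
#' @param config named list, or path to a YAML file with the layout
#'   above.
#' @return the manifest (named list), invisibly; also written as JSON.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (is.null(config$outDir)) "metaboflow_out" else config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  enabled <- function(s) isTRUE(st[[s]]$enabled)
  manifest <- list(seed = seed, outDir = outDir, stages = list())
  # upstream-artifact validation before any work
  for (f in c(config$input$mzml, config$input$table, config$input$design,
              config$input$peaklist, config$input$library)) {
    if (!is.null(f) && !file.exists(f))
      stop("configuration error: input file not found: ", f)
  }
  if ((enabled("trim") || enabled("optimize") || enabled("pick")) &&
      is.null(config$input$mzml))
    stop("configuration error: trim/optimize/pick enabled without input$mzml")
  if (enabled("correct") &&
      (is.null(config$input$table) || is.null(config$input$design)) &&
      !enabled("pick"))
    stop("configuration error: correct enabled without a feature table ",
         "(input$table + input$design, or an enabled pick stage)")
  if (enabled("enrich") &&
      (is.null(config$input$peaklist) || is.null(config$input$library)))
    stop("configuration error: enrich enabled without a peak table ",
         "(input$peaklist) and pathway library (input$library)")

  record <- function(name, params, outputs, t0) {
    manifest$stages[[name]] <<- list(
      params = params, outputs = outputs,
      md5 = as.list(tools::md5sum(unlist(outputs))),
      seconds = round(as.numeric(Sys.time()) - t0, 3))
  }
  runs <- NULL
  loadRuns <- function() {
    if (is.null(runs)) runs <<- lapply(config$input$mzml, readSpectra)
    runs
  }
  trimmed <- NULL
  if (enabled("trim")) {
    t0 <- as.numeric(Sys.time())
    p <- st$trim
    spec <- trimSpec(nBins = if (is.null(p$nBins)) 4L else p$nBins,
                     rtFraction = if (is.null(p$rtFraction)) 0.25 else p$rtFraction)
    trimmed <- lapply(loadRuns(), function(r) trimRun(r, spec))
    outs <- character()
    for (r in trimmed) {
      f <- file.path(outDir, paste0(r@sampleId, "_trimmed.mzML"))
      writeSpectra(r, f)
      outs <- c(outs, f)
    }
    record("trim", p, as.list(outs), t0)
  }
  params <- NULL
  if (enabled("optimize")) {
    t0 <- as.numeric(Sys.time())
    p <- st$optimize
    init <- platformDefaults(if (is.null(p$platform)) "generic" else p$platform)
    optRuns <- if (!is.null(trimmed)) trimmed else loadRuns()
    res <- optimizeParams(optRuns, init,
                          maxRounds = if (is.null(p$maxRounds)) 6L else p$maxRounds)
    params <- res$bestParams
    f <- file.path(outDir, "best_params.yaml")
    yaml::write_yaml(paramsAsList(params), f)
    fh <- file.path(outDir, "history.json")
    hist <- lapply(res$history, function(h)
      list(responses = h$responses, bestQs = h$bestQs,
           surfaceOptimum = as.list(h$surfaceOptimum)))
    jsonlite::write_json(hist, fh, auto_unbox = TRUE, digits = NA)
    record("optimize", p, list(f, fh), t0)
  }
  tableFile <- config$input$table
  if (enabled("pick")) {
    t0 <- as.numeric(Sys.time())
    p <- st$pick
    if (is.null(params))
      params <- if (!is.null(p$platform)) platformDefaults(p$platform) else platformDefaults("generic")
    peaks <- lapply(loadRuns(), pickPeaks, params = params)
    fs <- groupAndAlign(peaks, params)
    fs <- detectIsotopes(fs)
    tab <- cbind(featureTable(fs), featureIntensities(fs))
    colnames(tab)[-seq_len(ncol(featureTable(fs)))] <-
      vapply(loadRuns(), sampleId, character(1))
    f <- file.path(outDir, "feature_table.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    if (is.null(tableFile)) tableFile <- f  # an explicit input table wins
    record("pick", p, list(f), t0)
  }
  if (enabled("correct")) {
    t0 <- as.numeric(Sys.time())
    p <- st$correct
    if (is.null(tableFile) || is.null(config$input$design))
      stop("configuration error: correct stage has no feature table/design")
    tab <- utils::read.delim(tableFile, check.names = FALSE)
    des <- designFromFrame(utils::read.delim(config$input$design))
    numCols <- designAsFrame(des)$sample_id
    mat <- as.matrix(tab[, numCols, drop = FALSE])
    cand <- if (is.null(p$candidates)) c("eigenms", "combat", "qc_rlsc", "none")
            else unlist(p$candidates)
    res <- selectBestCorrection(mat, des, candidates = cand, seed = seed)
    f <- file.path(outDir, "corrected.tsv")
    utils::write.table(cbind(tab[, setdiff(names(tab), numCols), drop = FALSE],
                             res$corrected),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    fr <- file.path(outDir, "correction_report.json")
    jsonlite::write_json(list(method = res$method, score = res$score,
                              ordination = res$ordination,
                              gradientLength = res$gradientLength,
                              log = res$log),
                         fr, auto_unbox = TRUE, digits = NA)
    record("correct", p, list(f, fr), t0)
  }
  if (enabled("enrich")) {
    t0 <- as.numeric(Sys.time())
    p <- st$enrich
    peaklist <- utils::read.delim(config$input$peaklist)
    lib <- jsonlite::read_json(config$input$library, simplifyVector = TRUE)
    mp <- mummichogParams(
      ppm = if (is.null(p$ppm)) 10 else p$ppm,
      mode = if (is.null(p$mode)) "positive" else p$mode,
      pCutoff = if (is.null(p$pCutoff)) 0.05 else p$pCutoff,
      seed = seed)
    cmpds <- data.frame(id = lib$compounds$id, mass = lib$compounds$mass)
    res <- enrichMummichog(peaklist, lib$pathways, cmpds, mp)
    f <- file.path(outDir, "pathways.tsv")
    utils::write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    record("enrich", p, list(f), t0)
  }
  mf <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
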