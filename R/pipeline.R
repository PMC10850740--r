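#' @include AllClasses.R AllGenerics.R
NULL

# Accept a YAML file path or an already-parsed list; fill defaults.
.normalizeRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config$thresholds <- utils::modifyList(
    list(fold = 2, alpha = 0.05, bh = FALSE),
    config$thresholds %||% list())
  config$tracking <- utils::modifyList(
    list(ref = "Pre", cmp = "PC"), config$tracking %||% list())
  if (!is.null(config$markers))
    config$markers <- utils::modifyList(
      list(baseline = "Pre", base = 10), config$markers)
  config$outputDir <- config$outputDir %||% "repdyn-out"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Statically validate a run configuration
#'
#' Checks the configuration document (paths, labels, threshold ranges)
#' without touching any heavy computation. An empty return value means the
#' configuration is runnable.
#'
#' @param config a run configuration: a YAML file path or a list with
#'   elements `samples` (each with `patient`, `timepoint`, `compartment`,
#'   `path`), optional `comparisons` (pairs of timepoint labels), optional
#'   `thresholds` (`fold`, `alpha`, `bh`), optional `tracking`
#'   (`ref`, `cmp`), optional `markers` (`path`, `baseline`, `base`,
#'   optional `llodPath`), `outputDir` and `seed`.
#' @return character vector of problems (empty when runnable).
#' @export
validateConfig <- function(config) {
  config <- .normalizeRunConfig(config)
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))

  if (is.null(config$samples) || length(config$samples) == 0L) {
    note("config lists no samples")
  } else {
    labels <- character(0)
    for (i in seq_along(config$samples)) {
      s <- config$samples[[i]]
      for (f in c("patient", "timepoint", "compartment", "path"))
        if (is.null(s[[f]]))
          note("sample %d is missing field '%s'", i, f)
      if (!is.null(s$path) && !file.exists(s$path))
        note("sample %d: path '%s' does not exist", i, s$path)
      labels <- c(labels, s$timepoint %||% NA_character_)
    }
    for (pair in config$comparisons %||% list()) {
      if (length(pair) != 2L) {
        note("comparison '%s' is not a label pair",
             paste(unlist(pair), collapse = ","))
        next
      }
      for (lab in unlist(pair))
        if (!lab %in% labels)
          note("comparison label '%s' does not appear in the manifest", lab)
    }
  }
  th <- config$thresholds
  if (!is.numeric(th$fold) || th$fold <= 0)
    note("thresholds.fold must be > 0 (got %s)", format(th$fold))
  if (!is.numeric(th$alpha) || th$alpha <= 0 || th$alpha >= 1)
    note("thresholds.alpha must lie in (0, 1) (got %s)", format(th$alpha))
  mk <- config$markers
  if (!is.null(mk)) {
    if (is.null(mk$path) || !file.exists(mk$path))
      note("markers.path '%s' does not exist", mk$path %||% "<missing>")
    if (!mk$base %in% c(2, 10))
      note("markers.base must be 2 or 10")
    if (!is.null(mk$llodPath) && !file.exists(mk$llodPath))
      note("markers.llodPath '%s' does not exist", mk$llodPath)
  }
  problems
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full repertoire-kinetics pipeline
#'
#' Executes, from one configuration, the study-shaped analysis: sample
#' ingestion and QC, per-sample diversity (Simpson index, clone and
#' template totals), pairwise Morisita-Horn overlap, expansion calls for
#' every configured comparison within each patient/compartment series,
#' expanded-clone tracking from the anchor comparison, and
#' baseline-relative marker log fold-changes. Stages whose inputs are
#' absent (a single sample, no marker table) are reported as skipped, not
#' errors. Re-running with identical inputs overwrites the outputs with
#' identical content (the report timestamp aside).
#'
#' @param config see [validateConfig()].
#' @return Invisibly, the run report (also written to `report.json` in the
#'   output directory): per-stage status and output paths, per-sample QC,
#'   parameter echo, package version and seed.
#' @export
runPipeline <- function(config) {
  config <- .normalizeRunConfig(config)
  problems <- validateConfig(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  outDir <- config$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dialect <- config$io$dialect %||% defaultDialect()
  report <- list(
    package = "repdyn",
    version = as.character(utils::packageVersion("repdyn")),
    seed = config$seed %||% NA,
    parameters = list(thresholds = config$thresholds,
                      tracking = config$tracking,
                      timepointWeeks = as.list(timepointWeeks())),
    stages = list(), qc = list())
  stage <- function(name, status, outputs = character(0), extra = list())
    c(list(name = name, status = status,
           outputs = as.list(basename(outputs))), extra)

  ## ingest ----------------------------------------------------------------
  tables <- list()
  for (s in config$samples) {
    tab <- tryCatch(
      readCloneTable(s$path, dialect = dialect,
                     sampleId = paste(s$patient, s$timepoint,
                                      s$compartment, sep = "_"),
                     patientId = s$patient, timepoint = s$timepoint,
                     compartment = s$compartment),
      error = function(e) stop("stage 'ingest' failed on sample '",
                               s$path, "': ", conditionMessage(e)))
    tables[[sampleId(tab)]] <- tab
    report$qc[[sampleId(tab)]] <- list(
      nClones = productiveCount(tab),
      totalTemplates = totalTemplates(tab),
      discarded = discardedTally(tab))
  }
  report$stages <- c(report$stages, list(stage("ingest", "ok")))

  ## diversity -------------------------------------------------------------
  div <- do.call(rbind, lapply(tables, function(t) data.frame(
    sampleId = sampleId(t), patientId = patientId(t),
    timepoint = timepoint(t), compartment = compartment(t),
    nClones = productiveCount(t), totalTemplates = totalTemplates(t),
    simpson = simpsonIndex(t), discarded = discardedTally(t),
    stringsAsFactors = FALSE)))
  divPath <- .writeTsv(div, file.path(outDir, "diversity.tsv"))
  report$stages <- c(report$stages, list(stage("diversity", "ok", divPath)))

  ## overlap ---------------------------------------------------------------
  if (length(tables) >= 2L) {
    om <- overlapMatrix(tables)
    mPath <- file.path(outDir, "overlap_matrix.tsv")
    utils::write.table(om, mPath, sep = "\t", quote = FALSE,
                       col.names = NA)
    pairs <- which(upper.tri(om), arr.ind = TRUE)
    long <- data.frame(sampleA = rownames(om)[pairs[, 1L]],
                       sampleB = colnames(om)[pairs[, 2L]],
                       morisita = om[pairs], stringsAsFactors = FALSE)
    lPath <- .writeTsv(long, file.path(outDir, "overlap.tsv"))
    report$stages <- c(report$stages,
                       list(stage("overlap", "ok", c(lPath, mPath))))
  } else {
    report$stages <- c(report$stages,
                       list(stage("overlap", "skipped",
                                  extra = list(reason = "fewer than 2 samples"))))
  }

  ## series per patient x compartment ---------------------------------------
  meta <- data.frame(
    patient = vapply(tables, patientId, character(1)),
    compartment = vapply(tables, compartment, character(1)),
    timepoint = vapply(tables, timepoint, character(1)),
    id = names(tables), stringsAsFactors = FALSE)
  seriesKeys <- unique(meta[, c("patient", "compartment")])
  seriesList <- lapply(seq_len(nrow(seriesKeys)), function(i) {
    sel <- meta$patient == seriesKeys$patient[i] &
      meta$compartment == seriesKeys$compartment[i]
    tabs <- tables[meta$id[sel]]
    names(tabs) <- meta$timepoint[sel]
    SampleSeries(tabs, patientId = seriesKeys$patient[i])
  })

  ## expansion calls --------------------------------------------------------
  th <- config$thresholds
  callPaths <- character(0)
  nExpanded <- list()
  for (pair in config$comparisons %||% list()) {
    refLab <- pair[[1L]]; cmpLab <- pair[[2L]]
    for (ser in seriesList) {
      if (!all(c(refLab, cmpLab) %in% timepoints(ser))) next
      calls <- callExpansions(ser[[refLab]], ser[[cmpLab]],
                              foldThreshold = th$fold, alpha = th$alpha,
                              bh = isTRUE(th$bh))
      fn <- sprintf("calls_%s_%s_%s_vs_%s.tsv", patientId(ser),
                    compartment(ser[[refLab]]), refLab, cmpLab)
      callPaths <- c(callPaths, .writeTsv(calls, file.path(outDir, fn)))
      nExpanded[[fn]] <- sum(calls$expanded)
    }
  }
  report$stages <- c(report$stages, list(
    if (length(callPaths))
      stage("expansion", "ok", callPaths,
            extra = list(expandedCounts = nExpanded))
    else stage("expansion", "skipped",
               extra = list(reason = "no runnable comparison"))))

  ## tracking ---------------------------------------------------------------
  tr <- config$tracking
  trackRows <- list()
  for (ser in seriesList) {
    if (!all(c(tr$ref, tr$cmp) %in% timepoints(ser))) next
    ts <- trackExpanded(ser, anchorRef = tr$ref, anchorCmp = tr$cmp,
                        foldThreshold = th$fold, alpha = th$alpha,
                        bh = isTRUE(th$bh))
    af <- aggregateFrequency(ts)
    trackRows[[length(trackRows) + 1L]] <- data.frame(
      patientId = patientId(ts),
      compartment = compartment(ser[[tr$ref]]),
      anchor = paste(tr$ref, "vs", tr$cmp),
      nMembers = length(members(ts)),
      timepoint = names(af), aggregateFrequency = unname(af),
      stringsAsFactors = FALSE)
  }
  if (length(trackRows)) {
    tPath <- .writeTsv(do.call(rbind, trackRows),
                       file.path(outDir, "tracked.tsv"))
    report$stages <- c(report$stages, list(stage("tracking", "ok", tPath)))
  } else {
    report$stages <- c(report$stages, list(
      stage("tracking", "skipped",
            extra = list(reason = "anchor labels absent from every series"))))
  }

  ## markers ----------------------------------------------------------------
  if (!is.null(config$markers)) {
    mk <- config$markers
    long <- utils::read.csv(mk$path, stringsAsFactors = FALSE)
    llod <- numeric(0)
    if (!is.null(mk$llodPath)) {
      lt <- utils::read.csv(mk$llodPath, stringsAsFactors = FALSE)
      llod <- stats::setNames(as.numeric(lt[[2L]]), lt[[1L]])
    }
    am <- AnalyteMatrix(long, llod = llod)
    lfc <- logFoldChange(am, baseline = mk$baseline, base = mk$base)
    v <- analyteValues(lfc)
    out <- expand.grid(subject = subjects(lfc), analyte = analytes(lfc),
                       timepoint = timepoints(lfc),
                       stringsAsFactors = FALSE)
    out$logFC <- as.vector(v)
    mPath <- file.path(outDir, "logfc.csv")
    utils::write.csv(out, mPath, row.names = FALSE, quote = FALSE)
    report$stages <- c(report$stages, list(
      stage("markers", "ok", mPath,
            extra = list(logBase = mk$base, baseline = mk$baseline,
                         flooredBelowLLOD = lfc@flooredCount))))
  } else {
    report$stages <- c(report$stages, list(
      stage("markers", "skipped",
            extra = list(reason = "no marker table configured"))))
  }

  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Write a simulated study to disk
#'
#' Runs [simulateSeries()] and [simulateAnalytes()] and writes the results
#' the way a real study arrives: one clone-table TSV per sample named
#' `<patient>_<timepoint>_<compartment>.tsv`, a long-format `analytes.csv`,
#' an `llod.csv`, and `ground_truth.json`. Identical config and seed give
#' byte-identical files.
#'
#' @param config a valid [SimulationConfig-class].
#' @param outDir output directory (created if needed).
#' @param patientId patient label for the simulated subject's repertoire.
#' @return Invisibly, a list with the sample `manifest` (data.frame with
#'   `patient`, `timepoint`, `compartment`, `path`), the analyte/llod csv
#'   paths and the ground-truth path.
#' @export
simulateToFiles <- function(config, outDir, patientId = "SIM1") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateSeries(config, patientId = patientId)
  manifest <- list()
  for (comp in names(sim$series)) {
    ser <- sim$series[[comp]]
    for (tp in timepoints(ser)) {
      fn <- file.path(outDir,
                      sprintf("%s_%s_%s.tsv", patientId, tp, comp))
      writeCloneTable(ser[[tp]], fn)
      manifest[[length(manifest) + 1L]] <- data.frame(
        patient = patientId, timepoint = tp, compartment = comp,
        path = fn, stringsAsFactors = FALSE)
    }
  }
  ana <- simulateAnalytes(config)
  v <- analyteValues(ana$matrix)
  long <- expand.grid(subject = subjects(ana$matrix),
                      analyte = analytes(ana$matrix),
                      timepoint = timepoints(ana$matrix),
                      stringsAsFactors = FALSE)
  long$value <- as.vector(v)
  anaPath <- file.path(outDir, "analytes.csv")
  utils::write.csv(long, anaPath, row.names = FALSE, quote = FALSE)
  llod <- llodValues(ana$matrix)
  llodPath <- file.path(outDir, "llod.csv")
  utils::write.csv(data.frame(analyte = names(llod),
                              llod = unname(llod)),
                   llodPath, row.names = FALSE, quote = FALSE)
  truthPath <- file.path(outDir, "ground_truth.json")
  jsonlite::write_json(
    list(expanded = sim$truth$expanded,
         analyteEffects = as.data.frame(ana$truth)),
    truthPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = do.call(rbind, manifest),
                 analytes = anaPath, llod = llodPath,
                 groundTruth = truthPath,
                 truth = sim$truth, series = sim$series))
}
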