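#' @include AllClasses.R
NULL

#' Accessors for repdyn classes
#'
#' Getter functions for the slots of [CloneTable-class],
#' [SampleSeries-class], [AnalyteMatrix-class] and
#' [TrackedCloneSet-class]. Slots are never accessed with `@` in user code.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))
#' @rdname accessors
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))
#' @rdname accessors
#' @export
setGeneric("cloneCounts", function(x) standardGeneric("cloneCounts"))
#' @rdname accessors
#' @export
setGeneric("cloneFrequencies",
           function(x) standardGeneric("cloneFrequencies"))
#' @rdname accessors
#' @export
setGeneric("totalTemplates", function(x) standardGeneric("totalTemplates"))
#' @rdname accessors
#' @export
setGeneric("discardedTally", function(x) standardGeneric("discardedTally"))
#' @rdname accessors
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))
#' @rdname accessors
#' @export
setGeneric("seriesTables", function(x) standardGeneric("seriesTables"))
#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
#' @rdname accessors
#' @export
setGeneric("analytes", function(x) standardGeneric("analytes"))
#' @rdname accessors
#' @export
setGeneric("analyteValues", function(x) standardGeneric("analyteValues"))
#' @rdname accessors
#' @export
setGeneric("llodValues", function(x) standardGeneric("llodValues"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("aggregateFrequency",
           function(x) standardGeneric("aggregateFrequency"))
#' @rdname accessors
#' @export
setGeneric("anchorLabels", function(x) standardGeneric("anchorLabels"))

#' Simpson clonality index
#'
#' @param x a [CloneTable-class] or a numeric vector of clone counts or
#'   frequencies (normalized internally).
#' @param ... passed to methods.
#' @export
setGeneric("simpsonIndex", function(x, ...) standardGeneric("simpsonIndex"))

## CloneTable ---------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("sampleId", "CloneTable", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("patientId", "CloneTable", function(x) x@patientId)
#' @rdname accessors
#' @export
setMethod("timepoint", "CloneTable", function(x) x@timepoint)
#' @rdname accessors
#' @export
setMethod("compartment", "CloneTable", function(x) x@compartment)
#' @rdname accessors
#' @export
setMethod("cloneCounts", "CloneTable", function(x) {
  stats::setNames(x@clones$count, x@clones$cdr3aa)
})
#' @rdname accessors
#' @export
setMethod("cloneFrequencies", "CloneTable", function(x) {
  stats::setNames(x@clones$frequency, x@clones$cdr3aa)
})
#' @rdname accessors
#' @export
setMethod("totalTemplates", "CloneTable", function(x) x@totalCount)
#' @rdname accessors
#' @export
setMethod("discardedTally", "CloneTable", function(x) x@nDiscarded)

setMethod("show", "CloneTable", function(object) {
  cat(sprintf(
    "CloneTable '%s' (patient %s, %s/%s)\n  %d productive clones, %d templates, %d rows discarded on import\n",
    object@sampleId, object@patientId, object@timepoint,
    object@compartment, nrow(object@clones), object@totalCount,
    object@nDiscarded))
  top <- utils::head(object@clones[order(-object@clones$frequency,
                                         object@clones$cdr3aa), ], 3L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %s  %d  %.4g\n", top$cdr3aa[i], top$count[i],
                top$frequency[i]))
  if (nrow(object@clones) > 3L) cat("  ...\n")
})

## SampleSeries -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("patientId", "SampleSeries", function(x) x@patientId)
#' @rdname accessors
#' @export
setMethod("timepoints", "SampleSeries", function(x) x@timepoints)
#' @rdname accessors
#' @export
setMethod("seriesTables", "SampleSeries", function(x) x@tables)

#' @export
setMethod("length", "SampleSeries", function(x) length(x@tables))

#' Extract one table from a series by timepoint label or position
#' @param x a [SampleSeries-class]
#' @param i label or index
#' @export
setMethod("[[", "SampleSeries", function(x, i) x@tables[[i]])

setMethod("show", "SampleSeries", function(object) {
  cat(sprintf("SampleSeries for patient %s: %s\n", object@patientId,
              paste(object@timepoints, collapse = " < ")))
})

## AnalyteMatrix ------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("subjects", "AnalyteMatrix",
          function(x) dimnames(x@values)[[1L]])
#' @rdname accessors
#' @export
setMethod("analytes", "AnalyteMatrix",
          function(x) dimnames(x@values)[[2L]])
#' @rdname accessors
#' @export
setMethod("timepoints", "AnalyteMatrix",
          function(x) dimnames(x@values)[[3L]])
#' @rdname accessors
#' @export
setMethod("analyteValues", "AnalyteMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("llodValues", "AnalyteMatrix", function(x) x@llod)

setMethod("show", "AnalyteMatrix", function(object) {
  d <- dim(object@values)
  what <- if (object@isLogFC)
    sprintf("log%g fold-change vs baseline", object@logBase)
  else "measurements"
  cat(sprintf(
    "AnalyteMatrix: %d subjects x %d analytes x %d timepoints (%s)\n",
    d[1L], d[2L], d[3L], what))
  if (object@flooredCount > 0L)
    cat(sprintf("  %d below-LLOD values floored\n", object@flooredCount))
  cat(sprintf("  %d of %d values missing\n",
              sum(is.na(object@values)), length(object@values)))
})

## TrackedCloneSet ----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("patientId", "TrackedCloneSet", function(x) x@patientId)
#' @rdname accessors
#' @export
setMethod("members", "TrackedCloneSet", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("aggregateFrequency", "TrackedCloneSet",
          function(x) x@aggregateFrequency)
#' @rdname accessors
#' @export
setMethod("anchorLabels", "TrackedCloneSet",
          function(x) c(ref = x@anchorRef, cmp = x@anchorCmp))

setMethod("show", "TrackedCloneSet", function(object) {
  cat(sprintf(
    "TrackedCloneSet (patient %s): %d clones expanded in %s -> %s\n",
    object@patientId, length(object@members), object@anchorRef,
    object@anchorCmp))
  af <- object@aggregateFrequency
  cat("  aggregate frequency:",
      paste(sprintf("%s=%.4g", names(af), af), collapse = "  "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d clones (%s), %d timepoints, %d compartments, seed %d\n",
    object@nClones, object@abundanceModel, length(object@depth),
    length(object@compartments), object@seed))
  if (nrow(object@expansionSpec))
    cat(sprintf("  expansions: %s\n",
        paste(sprintf("%dx%g@%s", object@expansionSpec$nExpanded,
                      object@expansionSpec$fold,
                      object@expansionSpec$timepoint), collapse = ", ")))
})
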