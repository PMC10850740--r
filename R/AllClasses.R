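#' @import methods
NULL

# 20-letter amino-acid alphabet; '*' and 'X' mark non-productive rearrangements
# and never survive the productive filter.
.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Canonical blood-draw timepoint labels
#'
#' The study schema samples peripheral blood at four timepoints:
#' `Pre` (baseline, week 0), `PI` (post-immunotherapy, week 1),
#' `PC` (post-cryoablation, week 2) and `PS` (post-surgery, week 6).
#' Tissue-site labels live in the same namespace and sort after these.
#'
#' @return Character vector of the four canonical labels, in study order.
#' @export
#' @examples
#' timepointLevels()
timepointLevels <- function() c("Pre", "PI", "PC", "PS")

#' Canonical timepoint week mapping
#'
#' @return Named numeric vector mapping canonical labels to study week.
#' @export
timepointWeeks <- function() c(Pre = 0, PI = 1, PC = 2, PS = 6)

# Order labels by the canonical study schedule; unknown labels (tissue
# sites etc.) keep their input order after the canonical ones.
.orderTimepoints <- function(labels) {
  canon <- timepointLevels()
  key <- match(labels, canon)
  key[is.na(key)] <- length(canon) + seq_len(sum(is.na(key)))
  labels[order(key)]
}

#' CloneTable: one sample's processed TCR clone-abundance table
#'
#' An S4 container for a single sample's productive TCR repertoire: one row
#' per clone, where a clone is defined by its CDR3 amino-acid sequence, with
#' a template count and the within-sample frequency. Frequencies are always
#' recomputed from counts; duplicate CDR3 rows are aggregated by summing
#' counts at construction.
#'
#' @slot sampleId character(1), unique sample identifier.
#' @slot patientId character(1), subject the sample belongs to.
#' @slot timepoint character(1), canonical blood timepoint
#'   (`Pre`, `PI`, `PC`, `PS`) or a tissue-site label.
#' @slot compartment character(1), e.g. `blood`, `tumor_core`,
#'   `margin_1cm`, `margin_3cm`, `normal_tissue`.
#' @slot clones data.frame with columns `cdr3aa` (character), `count`
#'   (integer >= 1) and `frequency` (numeric, `count / totalCount`).
#' @slot totalCount integer(1), total productive templates in the sample.
#' @slot nDiscarded integer(1), rows dropped by the productive filter
#'   during import (0 for tables built in memory).
#'
#' @seealso [CloneTable()] for the constructor, [readCloneTable()] for
#'   file import.
#' @name CloneTable-class
#' @rdname CloneTable-class
#' @exportClass CloneTable
setClass("CloneTable",
  slots = c(
    sampleId    = "character",
    patientId   = "character",
    timepoint   = "character",
    compartment = "character",
    clones      = "data.frame",
    totalCount  = "integer",
    nDiscarded  = "integer"
  )
)

setValidity("CloneTable", function(object) {
  msgs <- character(0)
  for (s in c("sampleId", "patientId", "timepoint", "compartment")) {
    if (length(slot(object, s)) != 1L)
      msgs <- c(msgs, sprintf("'%s' must be length 1", s))
  }
  cl <- object@clones
  need <- c("cdr3aa", "count", "frequency")
  if (!all(need %in% names(cl)))
    return(paste("clones must have columns", paste(need, collapse = ", ")))
  if (nrow(cl) == 0L)
    return("a CloneTable must contain at least one clone")
  if (anyDuplicated(cl$cdr3aa))
    msgs <- c(msgs, "clone CDR3aa keys must be unique after aggregation")
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cl$cdr3aa)
  if (any(bad))
    msgs <- c(msgs, sprintf(
      "%d CDR3aa keys outside the productive amino-acid alphabet (e.g. '%s')",
      sum(bad), cl$cdr3aa[which(bad)[1L]]))
  if (!is.integer(cl$count) || any(cl$count < 1L))
    msgs <- c(msgs, "counts must be integers >= 1 after aggregation")
  if (sum(cl$count) != object@totalCount)
    msgs <- c(msgs, "sum of clone counts must equal totalCount")
  if (object@totalCount < 1L)
    msgs <- c(msgs, "totalCount must be positive")
  if (max(abs(cl$frequency - cl$count / object@totalCount)) > 1e-12)
    msgs <- c(msgs, "frequency must equal count / totalCount within 1e-12")
  if (abs(sum(cl$frequency) - 1) > 1e-9)
    msgs <- c(msgs, "frequencies must sum to 1 within 1e-9")
  if (object@nDiscarded < 0L)
    msgs <- c(msgs, "nDiscarded must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CloneTable from clone counts
#'
#' Duplicate CDR3 keys are aggregated by summing their counts (the clone
#' identity is the CDR3 amino-acid sequence alone); frequencies are computed
#' from the aggregated counts.
#'
#' @param counts named numeric vector of non-negative template counts; names
#'   are CDR3 amino-acid sequences. Zero-count entries are dropped.
#' @param sampleId,patientId,timepoint,compartment sample metadata.
#' @param nDiscarded integer tally of rows removed by the productive filter
#'   (used by [readCloneTable()]).
#' @return A validated [CloneTable-class] object.
#' @export
#' @examples
#' tab <- CloneTable(c(CASSLGETQYF = 8, CASRDRGNTIYF = 1, CSARDLNEQFF = 1))
#' cloneFrequencies(tab)
CloneTable <- function(counts, sampleId = "sample", patientId = "patient",
                       timepoint = NA_character_, compartment = "blood",
                       nDiscarded = 0L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be a named vector (names are CDR3aa sequences)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 0))
    stop("counts must be whole numbers")
  counts <- counts[counts > 0]
  if (length(counts) == 0L)
    stop("no clones with positive counts")
  agg <- tapply(as.numeric(counts), names(counts), sum)
  cdr3 <- sort(names(agg))
  cnt <- as.integer(agg[cdr3])
  total <- sum(cnt)
  new("CloneTable",
      sampleId = as.character(sampleId),
      patientId = as.character(patientId),
      timepoint = as.character(timepoint),
      compartment = as.character(compartment),
      clones = data.frame(cdr3aa = cdr3, count = cnt,
                          frequency = cnt / total,
                          stringsAsFactors = FALSE),
      totalCount = as.integer(total),
      nDiscarded = as.integer(nDiscarded))
}

#' SampleSeries: a patient's ordered collection of clone tables
#'
#' Holds the [CloneTable-class] objects of one patient keyed by timepoint or
#' tissue-site label, ordered by the canonical study schedule
#' (`Pre < PI < PC < PS`, tissue labels after).
#'
#' @slot patientId character(1).
#' @slot timepoints character, ordered labels.
#' @slot tables named list of [CloneTable-class], names equal to
#'   `timepoints`, all sharing `patientId`.
#'
#' @name SampleSeries-class
#' @rdname SampleSeries-class
#' @exportClass SampleSeries
setClass("SampleSeries",
  slots = c(
    patientId  = "character",
    timepoints = "character",
    tables     = "list"
  )
)

setValidity("SampleSeries", function(object) {
  msgs <- character(0)
  if (length(object@patientId) != 1L)
    msgs <- c(msgs, "'patientId' must be length 1")
  if (!identical(names(object@tables), object@timepoints))
    msgs <- c(msgs, "names(tables) must equal timepoints, in order")
  if (!all(vapply(object@tables, is, logical(1), "CloneTable")))
    return("all series members must be CloneTable objects")
  pats <- vapply(object@tables, function(t) t@patientId, character(1))
  if (length(pats) && !all(pats == object@patientId))
    msgs <- c(msgs, "all member tables must share the series patientId")
  canon <- object@timepoints[object@timepoints %in% timepointLevels()]
  if (!identical(canon, intersect(timepointLevels(), canon)))
    msgs <- c(msgs, "canonical timepoints must appear in study order")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SampleSeries
#'
#' @param tables named list of [CloneTable-class] objects; names are
#'   timepoint / site labels. Canonical labels are reordered to study order.
#' @param patientId patient identifier; defaults to the common patientId of
#'   the member tables.
#' @return A validated [SampleSeries-class] object.
#' @export
SampleSeries <- function(tables, patientId = NULL) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("'tables' must be a named list keyed by timepoint label")
  if (is.null(patientId)) {
    pats <- unique(vapply(tables, function(t) t@patientId, character(1)))
    if (length(pats) != 1L)
      stop("member tables carry different patient ids; pass 'patientId'")
    patientId <- pats
  }
  ord <- .orderTimepoints(names(tables))
  tables <- tables[ord]
  new("SampleSeries", patientId = as.character(patientId),
      timepoints = ord, tables = tables)
}

#' AnalyteMatrix: subject x analyte x timepoint immune-marker grid
#'
#' Stores flow-cytometry population frequencies (percent of parent) or serum
#' cytokine concentrations (pg/ml) on a subject x analyte x timepoint grid,
#' with optional per-analyte lower limits of detection (LLOD). The same
#' container holds baseline-relative log fold-change values after
#' [logFoldChange()]; `isLogFC` distinguishes the two (raw measurements must
#' be non-negative, log fold-changes may be negative).
#'
#' @slot values 3-d numeric array with dimnames `subject`, `analyte`,
#'   `timepoint`; `NA` marks missing measurements.
#' @slot llod named numeric vector of lower limits of detection, one entry
#'   per analyte that has a declared LLOD (may be empty).
#' @slot isLogFC logical(1), whether values are log fold-changes.
#' @slot logBase numeric(1), the log base used (NA for raw measurements).
#' @slot flooredCount integer(1), number of below-LLOD values floored during
#'   the log fold-change transform.
#'
#' @name AnalyteMatrix-class
#' @rdname AnalyteMatrix-class
#' @exportClass AnalyteMatrix
setClass("AnalyteMatrix",
  slots = c(
    values       = "array",
    llod         = "numeric",
    isLogFC      = "logical",
    logBase      = "numeric",
    flooredCount = "integer"
  )
)

setValidity("AnalyteMatrix", function(object) {
  msgs <- character(0)
  v <- object@values
  if (length(dim(v)) != 3L)
    return("values must be a 3-d array (subject x analyte x timepoint)")
  dn <- dimnames(v)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    msgs <- c(msgs, "values must carry full dimnames")
  if (!object@isLogFC && any(v < 0, na.rm = TRUE))
    msgs <- c(msgs, "measured values must be >= 0 or missing")
  if (length(object@llod) &&
      (is.null(names(object@llod)) ||
       !all(names(object@llod) %in% dn[[2L]])))
    msgs <- c(msgs, "llod names must be a subset of the analyte names")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnalyteMatrix
#'
#' @param values 3-d numeric array, subject x analyte x timepoint, with
#'   dimnames; or a long data.frame with columns `subject`, `analyte`,
#'   `timepoint`, `value`.
#' @param llod optional named numeric vector of per-analyte lower limits of
#'   detection, in the same units as the values.
#' @return A validated [AnalyteMatrix-class] object.
#' @export
#' @examples
#' long <- expand.grid(subject = c("S1", "S2"), analyte = "IFNg",
#'                     timepoint = c("Pre", "PC"), stringsAsFactors = FALSE)
#' long$value <- c(1.2, 0.8, 3.1, 2.2)
#' AnalyteMatrix(long, llod = c(IFNg = 0.1))
AnalyteMatrix <- function(values, llod = numeric(0)) {
  if (is.data.frame(values)) {
    need <- c("subject", "analyte", "timepoint", "value")
    if (!all(need %in% names(values)))
      stop("long-format input needs columns ",
           paste(need, collapse = ", "))
    subj <- unique(as.character(values$subject))
    ana <- unique(as.character(values$analyte))
    tp <- .orderTimepoints(unique(as.character(values$timepoint)))
    arr <- array(NA_real_, dim = c(length(subj), length(ana), length(tp)),
                 dimnames = list(subject = subj, analyte = ana,
                                 timepoint = tp))
    idx <- cbind(match(values$subject, subj), match(values$analyte, ana),
                 match(values$timepoint, tp))
    arr[idx] <- values$value
    values <- arr
  }
  new("AnalyteMatrix", values = values, llod = llod,
      isLogFC = FALSE, logBase = NA_real_, flooredCount = 0L)
}

#' TrackedCloneSet: expanded clones followed across a series
#'
#' The clones called expanded in one anchor comparison, with their aggregate
#' frequency at every timepoint of the series (0 where a member is absent).
#'
#' @slot patientId character(1).
#' @slot anchorRef,anchorCmp character(1), the anchor comparison labels
#'   (reference first).
#' @slot members character, CDR3aa sequences of the expanded clones.
#' @slot aggregateFrequency named numeric, summed member frequency per
#'   series timepoint.
#'
#' @name TrackedCloneSet-class
#' @rdname TrackedCloneSet-class
#' @exportClass TrackedCloneSet
setClass("TrackedCloneSet",
  slots = c(
    patientId          = "character",
    anchorRef          = "character",
    anchorCmp          = "character",
    members            = "character",
    aggregateFrequency = "numeric"
  )
)

setValidity("TrackedCloneSet", function(object) {
  msgs <- character(0)
  af <- object@aggregateFrequency
  if (is.null(names(af)))
    msgs <- c(msgs, "aggregateFrequency must be named by timepoint")
  if (any(af < -1e-12) || any(af > 1 + 1e-9))
    msgs <- c(msgs, "aggregate frequencies must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: full parameterization of the synthetic generator
#'
#' Every knob of the seeded synthetic longitudinal repertoire and analyte
#' generator. The same config plus the same seed always produces
#' byte-identical outputs. See [simulationConfig()] for defaults and the
#' meaning of each slot.
#'
#' @slot nClones integer, clones in the underlying true repertoire.
#' @slot abundanceModel `"zipf"` or `"lognormal"`.
#' @slot zipfExponent numeric, Zipf rank exponent (used when
#'   `abundanceModel == "zipf"`).
#' @slot lnMeanlog,lnSdlog numeric, lognormal abundance parameters.
#' @slot depth named integer, template totals per sampled timepoint.
#' @slot expansionSpec data.frame with columns `timepoint`, `nExpanded`,
#'   `fold`, `minBaseFreq`, `maxBaseFreq`: at each listed timepoint,
#'   `nExpanded` clones drawn from the given baseline-frequency stratum have
#'   their true frequency multiplied by `fold` (then renormalized).
#' @slot compartments character, compartment labels; the first is the
#'   expansion-carrying blood compartment.
#' @slot sShare numeric in `[0, 1]`, fraction of clone identities each
#'   non-blood compartment shares with blood.
#' @slot perturbSdlog numeric, lognormal sd of the frequency perturbation
#'   applied to shared clones in non-blood compartments.
#' @slot nSubjects integer, subjects for the analyte simulation.
#' @slot analyteSpec data.frame with columns `analyte`, `baselineMeanlog`,
#'   `baselineSdlog`, `noiseSdlog`, `llod` plus one `effect.<tp>` column per
#'   timepoint (multiplicative true effect relative to baseline).
#' @slot seed integer(1), mandatory RNG seed.
#'
#' @name SimulationConfig-class
#' @rdname SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    nClones       = "integer",
    abundanceModel = "character",
    zipfExponent  = "numeric",
    lnMeanlog     = "numeric",
    lnSdlog       = "numeric",
    depth         = "integer",
    expansionSpec = "data.frame",
    compartments  = "character",
    sShare        = "numeric",
    perturbSdlog  = "numeric",
    nSubjects     = "integer",
    analyteSpec   = "data.frame",
    seed          = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (object@nClones < 1L) msgs <- c(msgs, "nClones must be >= 1")
  if (!object@abundanceModel %in% c("zipf", "lognormal"))
    msgs <- c(msgs, "abundanceModel must be 'zipf' or 'lognormal'")
  if (is.null(names(object@depth)) || any(object@depth < 1L))
    msgs <- c(msgs, "depth must be a named vector of totals >= 1")
  es <- object@expansionSpec
  if (nrow(es)) {
    need <- c("timepoint", "nExpanded", "fold", "minBaseFreq", "maxBaseFreq")
    if (!all(need %in% names(es)))
      msgs <- c(msgs, paste("expansionSpec needs columns",
                            paste(need, collapse = ", ")))
    else {
      if (any(es$fold <= 0)) msgs <- c(msgs, "expansion fold must be > 0")
      if (any(es$nExpanded > object@nClones))
        msgs <- c(msgs, "more expanded clones requested than clones exist")
      if (!all(es$timepoint %in% names(object@depth)))
        msgs <- c(msgs, "expansionSpec timepoints must be sampled timepoints")
    }
  }
  if (object@sShare < 0 || object@sShare > 1)
    msgs <- c(msgs, "sShare must lie in [0, 1]")
  if (object@perturbSdlog < 0)
    msgs <- c(msgs, "perturbSdlog must be >= 0")
  as <- object@analyteSpec
  if (nrow(as)) {
    if (any(as$baselineSdlog < 0) || any(as$noiseSdlog < 0))
      msgs <- c(msgs, "analyte variance parameters must be >= 0")
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "a scalar integer seed is mandatory")
  if (length(msgs)) msgs else TRUE
})
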