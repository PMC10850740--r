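#' @include AllClasses.R AllGenerics.R
NULL

#' Default immunoSEQ-style column dialect
#'
#' Header names vary across assay versions; each logical field maps to a
#' vector of accepted header names, first match wins. Extra columns in the
#' input (nucleotide rearrangement, V/J gene calls, vendor frequencies) are
#' ignored: clone identity is the CDR3 amino-acid sequence alone and
#' frequencies are always recomputed from template counts.
#'
#' @return Named list with elements `cdr3`, `count` and `frame` (the frame
#'   column is optional in the input).
#' @export
defaultDialect <- function() {
  list(
    cdr3  = c("cdr3_amino_acid", "amino_acid", "aminoAcid", "cdr3aa"),
    count = c("templates", "count (templates/reads)", "count",
              "templates_reads", "seq_reads"),
    frame = c("frame_type", "frame", "sequenceStatus")
  )
}

# Productive-frame values accepted for the optional frame column.
.PRODUCTIVE_FRAME <- c("in", "in-frame", "inframe", "productive")

#' Read a processed clone-abundance table
#'
#' Reads a tab-separated clone table (one sample), applies the productive
#' filter, aggregates rows sharing a CDR3 amino-acid sequence by summing
#' template counts, and recomputes frequencies from the post-filter total.
#'
#' The productive filter drops rows whose CDR3 is empty, contains a stop
#' codon (`*`) or undetermined residue (`X`), or whose frame column (when
#' present) is not in-frame/productive. The number of dropped rows is kept
#' in the returned table's discard tally.
#'
#' @param path path to a UTF-8 tab-separated file with a header row.
#' @param dialect column-name mapping as produced by [defaultDialect()];
#'   each logical field may list several accepted headers.
#' @param sampleId,patientId,timepoint,compartment sample metadata attached
#'   to the returned table; `sampleId` defaults to the file name.
#' @return A validated [CloneTable-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("cdr3_amino_acid\ttemplates",
#'              "CASSLGETQYF\t3", "CASSLGETQYF\t2"), f)
#' readCloneTable(f)  # one clone, count 5
#'
#' ex <- system.file("extdata", "synthetic_example_Pre_blood.tsv",
#'                   package = "repdyn")
#' readCloneTable(ex)  # 8 productive clones, 1 row discarded
readCloneTable <- function(path, dialect = defaultDialect(),
                           sampleId = basename(path),
                           patientId = "patient",
                           timepoint = NA_character_,
                           compartment = "blood") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  pick <- function(field, required = TRUE) {
    hit <- intersect(dialect[[field]], names(raw))
    if (length(hit) == 0L) {
      if (required)
        stop(sprintf(
          "format error in '%s': no column for '%s' (accepted: %s)",
          path, field, paste(dialect[[field]], collapse = ", ")))
      return(NULL)
    }
    hit[1L]
  }
  cdr3Col <- pick("cdr3")
  countCol <- pick("count")
  frameCol <- pick("frame", required = FALSE)

  cdr3 <- trimws(raw[[cdr3Col]])
  countChr <- trimws(raw[[countCol]])
  count <- suppressWarnings(as.numeric(countChr))
  bad <- which(is.na(count) | count < 0 | count != floor(count))
  if (length(bad))
    stop(sprintf(
      "validation error in '%s': row %d has invalid count '%s' (counts must be non-negative integers)",
      path, bad[1L], countChr[bad[1L]]))

  keep <- nzchar(cdr3) &
    grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cdr3) &
    count > 0
  if (!is.null(frameCol))
    keep <- keep & tolower(trimws(raw[[frameCol]])) %in% .PRODUCTIVE_FRAME
  nDiscard <- sum(!keep)
  if (!any(keep))
    stop(sprintf("empty sample: no productive rows survive in '%s'", path))

  CloneTable(stats::setNames(count[keep], cdr3[keep]),
             sampleId = sampleId, patientId = patientId,
             timepoint = timepoint, compartment = compartment,
             nDiscarded = nDiscard)
}

#' Write a clone-abundance table
#'
#' Writes the default tab-separated dialect (`cdr3_amino_acid`, `templates`,
#' `productive_frequency`). The file round-trips through [readCloneTable()]
#' to a table with identical clones and counts; frequencies are recomputed
#' on read, never trusted from the file.
#'
#' @param table a valid [CloneTable-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeCloneTable <- function(table, path) {
  stopifnot(is(table, "CloneTable"))
  validObject(table)
  out <- data.frame(
    cdr3_amino_acid = table@clones$cdr3aa,
    templates = table@clones$count,
    productive_frequency = format(table@clones$frequency, digits = 15,
                                  scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE)
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Number of distinct productive clones in a sample
#'
#' The per-sample productive-TCR summary statistic: the number of distinct
#' productive CDR3 amino-acid clones after aggregation (not the number of
#' input rows).
#'
#' @param table a valid [CloneTable-class].
#' @return integer(1).
#' @export
productiveCount <- function(table) {
  stopifnot(is(table, "CloneTable"))
  nrow(table@clones)
}
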