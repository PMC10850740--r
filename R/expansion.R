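#' @include AllClasses.R AllGenerics.R
NULL

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact two-sided p-value for the table `(a, b; c, d)` with fixed margins,
#' computed by direct enumeration of the hypergeometric support: the sum of
#' the probabilities of all tables whose probability does not exceed that of
#' the observed table (with the conventional `1 + 1e-7` relative tolerance
#' for floating-point ties). Deterministic and exact; no chi-square
#' approximation anywhere.
#'
#' In the expansion caller the table is `(count_ref, total_ref - count_ref;
#' count_cmp, total_cmp - count_cmp)`.
#'
#' @param a,b,c,d non-negative integer cell counts; both row sums
#'   `a + b` and `c + d` must be positive.
#' @return numeric(1) in `(0, 1]`.
#' @export
#' @examples
#' fisherExactP(5, 95, 5, 95)        # identical rows: 1
#' fisherExactP(10, 9990, 40, 9960)  # clone 10 -> 40 at depth 1e4
fisherExactP <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  m <- a + b
  n <- c + d
  if (m <= 0 || n <= 0) stop("degenerate margins: both row totals must be > 0")
  k <- a + c
  if (k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  dObs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= dObs * (1 + 1e-7)]))
}

#' Call significantly expanded clones between two samples
#'
#' For every clone in the union of the reference and comparison samples,
#' computes the frequency fold-change `freq_cmp / freq_ref` and the
#' two-sided Fisher exact p-value of the 2x2 template table
#' `(count_ref, total_ref - count_ref; count_cmp, total_cmp - count_cmp)`.
#' A clone is called expanded when its frequency increased by more than
#' `foldThreshold` AND the Fisher p-value is below `alpha`. The joint
#' criterion identifies clones expanded beyond sampling noise and filters
#' out large relative fluctuations in small clones, which fail the exact
#' test. Raw p-values are used by default (no multiple-testing correction);
#' set `bh = TRUE` to gate the call on Benjamini-Hochberg adjusted p-values
#' instead.
#'
#' Clones absent from the reference but present in the comparison get an
#' infinite fold-change and remain eligible for expansion on the Fisher
#' criterion alone; clones absent from the comparison (fold-change 0) are
#' never expanded.
#'
#' @param ref,cmp valid [CloneTable-class] objects (reference first; when
#'   driven from a time series the reference is the earlier sample).
#' @param foldThreshold numeric > 0, minimum fold increase (exclusive).
#' @param alpha numeric in (0, 1), significance level.
#' @param bh logical, gate the expanded call on BH-adjusted p-values.
#' @return data.frame, one row per union clone, sorted by ascending p then
#'   descending fold then CDR3aa, with columns `cdr3aa`, `countRef`,
#'   `countCmp`, `totalRef`, `totalCmp`, `freqRef`, `freqCmp`, `foldChange`,
#'   `log2FC` (NA where a frequency is 0), `pValue`, `pAdjusted` (only when
#'   `bh = TRUE`) and `expanded`. The comparison construction and thresholds
#'   are attached as `attr(, "parameters")`.
#' @export
callExpansions <- function(ref, cmp, foldThreshold = 2, alpha = 0.05,
                           bh = FALSE) {
  stopifnot(is(ref, "CloneTable"), is(cmp, "CloneTable"),
            foldThreshold > 0, alpha > 0, alpha < 1)
  cr <- cloneCounts(ref)
  cc <- cloneCounts(cmp)
  union <- sort(unique(c(names(cr), names(cc))))
  aRef <- as.numeric(cr[union]); aRef[is.na(aRef)] <- 0
  aCmp <- as.numeric(cc[union]); aCmp[is.na(aCmp)] <- 0
  totalRef <- totalTemplates(ref)
  totalCmp <- totalTemplates(cmp)
  freqRef <- aRef / totalRef
  freqCmp <- aCmp / totalCmp

  fold <- ifelse(freqRef > 0, freqCmp / freqRef,
                 ifelse(freqCmp > 0, Inf, NaN))
  log2fc <- ifelse(freqRef > 0 & freqCmp > 0, log2(freqCmp / freqRef),
                   NA_real_)

  # many clones share the same (countRef, countCmp) pair; compute each
  # distinct 2x2 table once
  key <- paste(aRef, aCmp)
  uniq <- !duplicated(key)
  pUniq <- mapply(function(a, c)
    fisherExactP(a, totalRef - a, c, totalCmp - c),
    aRef[uniq], aCmp[uniq])
  p <- unname(pUniq[match(key, key[uniq])])

  pGate <- if (bh) stats::p.adjust(p, method = "BH") else p
  expanded <- fold > foldThreshold & pGate < alpha
  expanded[is.na(expanded)] <- FALSE

  out <- data.frame(
    cdr3aa = union,
    countRef = as.integer(aRef), countCmp = as.integer(aCmp),
    totalRef = totalRef, totalCmp = totalCmp,
    freqRef = freqRef, freqCmp = freqCmp,
    foldChange = fold, log2FC = log2fc, pValue = p,
    stringsAsFactors = FALSE)
  if (bh) out$pAdjusted <- pGate
  out$expanded <- expanded
  out <- out[order(out$pValue, -out$foldChange, out$cdr3aa), ]
  rownames(out) <- NULL
  attr(out, "parameters") <- list(
    refSample = sampleId(ref), cmpSample = sampleId(cmp),
    foldThreshold = foldThreshold, alpha = alpha, bh = bh,
    table2x2 = "(cloneCount, allOtherTemplates) per sample")
  out
}

#' Volcano-plot data from expansion calls
#'
#' One row per clone with a finite, positive fold-change: `log2FC` against
#' `-log10(p)`, the latter capped at `cap` for plotting. Clones with an
#' infinite fold-change (absent from the reference) or fold-change 0
#' (absent from the comparison) cannot be placed on the log2 axis and are
#' returned in the `attr(, "nonfinite")` sidecar with their p-values.
#'
#' @param calls data.frame from [callExpansions()].
#' @param cap numeric, ceiling applied to `-log10(p)`.
#' @return data.frame with columns `cdr3aa`, `log2FC`, `negLog10P`,
#'   `expanded`; sidecar in `attr(, "nonfinite")`.
#' @export
volcanoData <- function(calls, cap = 50) {
  stopifnot(nrow(calls) > 0, cap > 0)
  finite <- is.finite(calls$log2FC)
  out <- data.frame(
    cdr3aa = calls$cdr3aa[finite],
    log2FC = calls$log2FC[finite],
    negLog10P = pmin(-log10(calls$pValue[finite]), cap),
    expanded = calls$expanded[finite],
    stringsAsFactors = FALSE)
  attr(out, "nonfinite") <- data.frame(
    cdr3aa = calls$cdr3aa[!finite],
    foldChange = calls$foldChange[!finite],
    pValue = calls$pValue[!finite],
    expanded = calls$expanded[!finite],
    stringsAsFactors = FALSE)
  out
}

#' Track expanded clones across a sample series
#'
#' Calls expansions on one anchor comparison (by default the later sample
#' against the earlier), then follows the expanded-clone set through every
#' timepoint of the series, reporting the summed frequency of the member
#' clones at each (0 where a member is absent).
#'
#' @param series a valid [SampleSeries-class].
#' @param anchorRef,anchorCmp labels present in the series; the comparison
#'   is `anchorCmp` vs `anchorRef`.
#' @param foldThreshold,alpha,bh passed to [callExpansions()].
#' @return A [TrackedCloneSet-class].
#' @export
trackExpanded <- function(series, anchorRef = "Pre", anchorCmp = "PC",
                          foldThreshold = 2, alpha = 0.05, bh = FALSE) {
  stopifnot(is(series, "SampleSeries"))
  for (lab in c(anchorRef, anchorCmp))
    if (!lab %in% timepoints(series))
      stop("anchor label '", lab, "' is not in the series")
  calls <- callExpansions(series[[anchorRef]], series[[anchorCmp]],
                          foldThreshold = foldThreshold, alpha = alpha,
                          bh = bh)
  mem <- sort(calls$cdr3aa[calls$expanded])
  agg <- vapply(timepoints(series), function(lab) {
    f <- cloneFrequencies(series[[lab]])
    sum(f[intersect(mem, names(f))])
  }, numeric(1))
  new("TrackedCloneSet", patientId = patientId(series),
      anchorRef = anchorRef, anchorCmp = anchorCmp,
      members = mem, aggregateFrequency = agg)
}
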