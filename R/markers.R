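#' @include AllClasses.R AllGenerics.R
NULL

#' Baseline-relative log fold-change of immune markers
#'
#' Describes the effect of therapy per subject and analyte as the log of
#' the fold change relative to baseline:
#' `log_base(value_t / value_baseline)`. The baseline column is 0 by
#' construction wherever the baseline is measured. Base 10 is the
#' convention for marker/cytokine heatmaps; base 2 for clone fold-changes.
#'
#' Values below a declared lower limit of detection are floored at the LLOD
#' before the transform and the number of floored values is recorded in the
#' result's `flooredCount` (shown by `show()`). Zeros of an analyte with no
#' declared LLOD produce missing log-FC (never `-Inf`); subjects whose
#' baseline is missing or zero-without-LLOD get missing log-FC at every
#' timepoint for that analyte.
#'
#' @param x a measurement [AnalyteMatrix-class] (not already log-FC).
#' @param baseline baseline timepoint label, default `"Pre"`.
#' @param base log base, 2 or 10.
#' @return An [AnalyteMatrix-class] of log fold-changes.
#' @export
logFoldChange <- function(x, baseline = "Pre", base = 10) {
  stopifnot(is(x, "AnalyteMatrix"), base %in% c(2, 10))
  if (x@isLogFC) stop("input already holds log fold-changes")
  if (!baseline %in% timepoints(x))
    stop("baseline label '", baseline, "' not in the matrix")
  v <- x@values
  nFloor <- 0L
  for (an in names(x@llod)) {
    low <- which(v[, an, ] < x@llod[[an]])
    nFloor <- nFloor + length(low)
    v[, an, ][low] <- x@llod[[an]]
  }
  v[v == 0] <- NA_real_  # no declared floor: zero cannot enter a log
  b <- v[, , baseline, drop = FALSE]
  lfc <- log(sweep(v, c(1, 2), b[, , 1L], "/"), base = base)
  lfc[, , baseline][!is.na(b[, , 1L])] <- 0  # exact zero, not fp residue
  new("AnalyteMatrix", values = lfc, llod = x@llod, isLogFC = TRUE,
      logBase = as.numeric(base), flooredCount = nFloor)
}

#' Cohort-average log fold-change per analyte and timepoint
#'
#' Arithmetic mean of per-subject log fold-changes for each analyte and
#' timepoint (the numbers behind cohort heatmaps), with the number of
#' contributing subjects per cell. All-missing cells are `NA` with `n = 0`.
#'
#' @param x a log-FC [AnalyteMatrix-class] from [logFoldChange()].
#' @return list with `mean` and `n`, both analyte x timepoint matrices.
#' @export
cohortMeanLogFC <- function(x) {
  stopifnot(is(x, "AnalyteMatrix"))
  if (!x@isLogFC) stop("input must hold log fold-changes; see logFoldChange()")
  m <- apply(x@values, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  n <- apply(x@values, c(2, 3), function(v) sum(!is.na(v)))
  list(mean = m, n = n)
}

#' Per-subject ratio of two analytes
#'
#' Elementwise ratio of two cell populations per subject and timepoint,
#' e.g. effector-to-regulatory (CD8 over Foxp3+CD4) or CD8 over CD4+PD-1hi.
#' Where the denominator is 0 or missing the ratio is missing (a warning
#' reports how many cells were affected); infinities never appear in
#' output tables.
#'
#' @param x a measurement [AnalyteMatrix-class].
#' @param numerator,denominator analyte names present in `x`.
#' @return subject x timepoint numeric matrix.
#' @export
cellRatio <- function(x, numerator, denominator) {
  stopifnot(is(x, "AnalyteMatrix"))
  for (an in c(numerator, denominator))
    if (!an %in% analytes(x)) stop("analyte '", an, "' not in the matrix")
  num <- x@values[, numerator, , drop = TRUE]
  den <- x@values[, denominator, , drop = TRUE]
  if (is.null(dim(num))) {  # single subject: keep matrix shape
    num <- matrix(num, nrow = 1,
                  dimnames = list(subjects(x), timepoints(x)))
    den <- matrix(den, nrow = 1,
                  dimnames = list(subjects(x), timepoints(x)))
  }
  zero <- !is.na(den) & den == 0
  if (any(zero))
    warning(sum(zero), " cell(s) with zero denominator set to missing")
  den[zero] <- NA_real_
  num / den
}

#' Paired t tests between two timepoints, per analyte
#'
#' Classical paired t test on per-subject differences
#' `value[labelB] - value[labelA]`, two-sided p from the t distribution
#' with `n - 1` degrees of freedom. Subjects missing either member of the
#' pair are excluded pairwise. Analytes with fewer than 2 complete pairs
#' get a missing result; zero-variance differences are flagged degenerate
#' (the p-value is reported missing, never 0 or 1 by fiat).
#'
#' @param x a measurement or log-FC [AnalyteMatrix-class].
#' @param labelA,labelB timepoint labels; the test is `labelB` vs `labelA`,
#'   so swapping labels negates `t` and preserves `p`.
#' @return data.frame with columns `analyte`, `t`, `p`, `n`, `degenerate`.
#' @export
pairedT <- function(x, labelA, labelB) {
  stopifnot(is(x, "AnalyteMatrix"))
  for (lab in c(labelA, labelB))
    if (!lab %in% timepoints(x)) stop("timepoint '", lab, "' not in matrix")
  res <- lapply(analytes(x), function(an) {
    va <- x@values[, an, labelA]
    vb <- x@values[, an, labelB]
    ok <- !is.na(va) & !is.na(vb)
    n <- sum(ok)
    if (n < 2L)
      return(data.frame(analyte = an, t = NA_real_, p = NA_real_, n = n,
                        degenerate = FALSE))
    d <- vb[ok] - va[ok]
    if (all(d == 0))  # identical pairs: no observed change
      return(data.frame(analyte = an, t = 0, p = 1, n = n,
                        degenerate = FALSE))
    fit <- tryCatch(stats::t.test(d), error = function(e) NULL)
    if (is.null(fit))  # constant nonzero differences: sd(d) == 0, t undefined
      return(data.frame(analyte = an, t = NA_real_, p = NA_real_, n = n,
                        degenerate = TRUE))
    data.frame(analyte = an, t = unname(fit$statistic),
               p = fit$p.value, n = n, degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
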