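#' @include AllClasses.R AllGenerics.R
NULL

#' Simpson clonality index
#'
#' The Simpson index of a repertoire is the sum of squared clone
#' frequencies, `sum(p_i^2)`: the probability of drawing the same clone
#' twice when sampling two TCRs at random (with replacement). It is higher
#' for more clonal, less diverse samples and equals `1/K` for a uniform
#' repertoire of `K` clones.
#'
#' The default matches the two-draw-with-replacement definition on
#' normalized frequencies. `unbiased = TRUE` gives the without-replacement
#' estimator `sum(n_i (n_i - 1)) / (N (N - 1))` on template counts; it is
#' not the default.
#'
#' @param x a [CloneTable-class], or a numeric vector of clone counts or
#'   frequencies (normalized internally).
#' @param unbiased logical, use the without-replacement estimator
#'   (CloneTable method only).
#' @param ... unused.
#' @return numeric(1) in `(0, 1]`.
#' @export
#' @examples
#' simpsonIndex(c(0.8, 0.1, 0.1))           # 0.66
#' simpsonIndex(CloneTable(c(CASSF = 1, CASTF = 1, CASGF = 1, CASHF = 1)))
setMethod("simpsonIndex", "CloneTable",
  function(x, unbiased = FALSE, ...) {
    if (unbiased) {
      n <- as.numeric(x@clones$count)
      N <- sum(n)
      if (N < 2) stop("unbiased estimator needs at least 2 templates")
      return(sum(n * (n - 1)) / (N * (N - 1)))
    }
    sum(x@clones$frequency^2)
  })

#' @rdname simpsonIndex-CloneTable-method
#' @export
setMethod("simpsonIndex", "numeric", function(x, ...) {
  if (length(x) == 0L || any(x < 0) || sum(x) <= 0)
    stop("'x' must be non-negative with positive sum")
  p <- x / sum(x)
  sum(p^2)
})

#' Rank-frequency structure of a repertoire
#'
#' Clones sorted by descending frequency (ties broken lexicographically by
#' CDR3aa for determinism), truncated to the `topN` most abundant, plus an
#' aggregated remainder row so the reported frequencies sum to 1. This is
#' the data behind stacked rank-abundance plots of the most abundant clones.
#'
#' @param table a valid [CloneTable-class].
#' @param topN integer >= 1, number of individually reported clones.
#' @return data.frame with columns `rank` (NA on the remainder row),
#'   `cdr3aa` (`"<remainder>"` on that row) and `frequency`.
#' @export
rankFrequency <- function(table, topN = 10L) {
  stopifnot(is(table, "CloneTable"), topN >= 1L)
  cl <- table@clones[order(-table@clones$frequency, table@clones$cdr3aa), ]
  n <- min(as.integer(topN), nrow(cl))
  top <- data.frame(rank = seq_len(n), cdr3aa = cl$cdr3aa[seq_len(n)],
                    frequency = cl$frequency[seq_len(n)],
                    stringsAsFactors = FALSE)
  rem <- if (nrow(cl) > n) sum(cl$frequency[-seq_len(n)]) else 0
  rbind(top, data.frame(rank = NA_integer_, cdr3aa = "<remainder>",
                        frequency = rem, stringsAsFactors = FALSE))
}

#' Morisita-Horn overlap between two repertoires
#'
#' Frequency-weighted similarity of two samples:
#' `2 * sum(x_i * y_i) / (sum(x_i^2) + sum(y_i^2))` over the union of
#' clones, with `x_i`, `y_i` the normalized clone frequencies (0 where a
#' clone is absent). The denominator is the sum of the two samples' Simpson
#' indices; the factor 2 makes identical samples score exactly 1, and
#' samples sharing no clone score exactly 0. The statistic is dominated by
#' large clones — perturbing the low-frequency tail moves it very little.
#'
#' @param a,b valid [CloneTable-class] objects.
#' @return numeric(1) in `[0, 1]`.
#' @export
#' @examples
#' x <- CloneTable(c(CASSF = 1, CASTF = 1))
#' y <- CloneTable(c(CASSF = 1, CASGF = 1))
#' morisitaOverlap(x, y)  # 0.5
morisitaOverlap <- function(a, b) {
  stopifnot(is(a, "CloneTable"), is(b, "CloneTable"))
  fa <- cloneFrequencies(a)
  fb <- cloneFrequencies(b)
  shared <- intersect(names(fa), names(fb))
  num <- 2 * sum(fa[shared] * fb[shared])
  num / (sum(fa^2) + sum(fb^2))
}

#' Pairwise Morisita-Horn overlap matrix
#'
#' @param tables list of >= 2 valid [CloneTable-class] objects with unique
#'   sample ids.
#' @return Symmetric numeric matrix in `[0, 1]` with unit diagonal,
#'   dimnames set to the sample ids.
#' @export
overlapMatrix <- function(tables) {
  stopifnot(length(tables) >= 2L,
            all(vapply(tables, is, logical(1), "CloneTable")))
  ids <- vapply(tables, sampleId, character(1))
  if (anyDuplicated(ids))
    stop("sample ids must be unique across tables")
  n <- length(tables)
  m <- diag(1, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- morisitaOverlap(tables[[i]], tables[[j]])
  dimnames(m) <- list(ids, ids)
  m
}
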