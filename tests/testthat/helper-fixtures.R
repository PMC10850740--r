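# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# n unique CDR3-like labels ('C' + k residues + 'F'), deterministic per seed
cdr3Labels <- function(n, seed = 1, len = 9) {
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n + 8), function(i)
      paste0("C", paste(sample(AA, len, replace = TRUE), collapse = ""), "F"),
      character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

# random clone table with nClones clones, counts 1..maxCount
randomTable <- function(nClones, seed, maxCount = 50, ...) {
  labels <- cdr3Labels(nClones, seed = seed)
  set.seed(seed + 1000)
  CloneTable(setNames(sample.int(maxCount, nClones, replace = TRUE), labels),
             ...)
}

# write a clone table TSV with the given header and rows, return the path
writeFixtureTsv <- function(lines, dir = tempdir()) {
  f <- tempfile(fileext = ".tsv", tmpdir = dir)
  writeLines(lines, f)
  f
}

# independent brute-force Morisita: explicit loop over the clone union
bruteMorisita <- function(a, b) {
  fa <- cloneFrequencies(a); fb <- cloneFrequencies(b)
  union <- unique(c(names(fa), names(fb)))
  num <- 0; sa <- 0; sb <- 0
  for (cl in union) {
    x <- if (cl %in% names(fa)) fa[[cl]] else 0
    y <- if (cl %in% names(fb)) fb[[cl]] else 0
    num <- num + x * y
    sa <- sa + x^2; sb <- sb + y^2
  }
  2 * num / (sa + sb)
}

# independent brute-force Simpson: explicit loop over clones
bruteSimpson <- function(tab) {
  f <- cloneFrequencies(tab)
  s <- 0
  for (cl in names(f)) s <- s + f[[cl]]^2
  s
}

# independent two-sided Fisher exact p by enumeration with the ratio
# recurrence P(x+1)/P(x) = (m-x)(k-x) / ((x+1)(n-k+x+1)); no dhyper anywhere
bruteFisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- numeric(hi - lo + 1)
  probs[1] <- 1
  x <- lo
  for (i in seq_len(hi - lo)) {
    probs[i + 1] <- probs[i] * (m - x) * (k - x) /
      ((x + 1) * (n - k + x + 1))
    x <- x + 1
  }
  probs <- probs / sum(probs)
  pObs <- probs[a - lo + 1]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
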