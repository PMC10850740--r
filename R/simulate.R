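#' @include AllClasses.R AllGenerics.R
NULL

# Synthetic CDR3-like labels: 'C' + 8-16 random residues + 'F', unique,
# so every fixture passes the productive filter.
.randomCDR3 <- function(n, exclude = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    len <- sample(8:16, k + 8L, replace = TRUE)
    cand <- vapply(len, function(L)
      paste0("C", paste(sample(.AA_ALPHABET, L, replace = TRUE),
                        collapse = ""), "F"), character(1))
    out <- setdiff(unique(c(out, setdiff(cand, exclude))), exclude)
  }
  out[seq_len(n)]
}

#' Default analyte panel for the synthetic generator
#'
#' A small panel emulating the study's gated flow populations (percent of
#' parent) and serum cytokines (pg/ml): CD8 and regulatory/PD-1hi CD4
#' fractions, and IFN-gamma / TNF-alpha concentrations with declared lower
#' limits of detection. True multiplicative effects peak in the first two
#' weeks after treatment and revert by week 6, the kinetics the analysis
#' is designed to resolve.
#'
#' @return data.frame with one row per analyte: lognormal baseline
#'   parameters, lognormal assay noise, LLOD (NA where none is declared)
#'   and the true effect per timepoint (`effect.Pre` .. `effect.PS`).
#' @export
defaultAnalyteSpec <- function() {
  data.frame(
    analyte = c("CD8", "Treg", "CD4PD1hi", "IFNg", "TNFa"),
    baselineMeanlog = log(c(25, 4, 2, 5, 2)),
    baselineSdlog = c(0.3, 0.3, 0.4, 0.5, 0.5),
    noiseSdlog = c(0.1, 0.1, 0.15, 0.25, 0.25),
    llod = c(NA, NA, NA, 0.2, 0.1),
    effect.Pre = c(1, 1, 1, 1, 1),
    effect.PI = c(1.2, 0.9, 1.5, 2.0, 1.6),
    effect.PC = c(1.3, 0.85, 1.8, 1.6, 1.3),
    effect.PS = c(1.05, 1.0, 1.2, 1.1, 1.0),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Parameterizes the seeded synthetic longitudinal generator. The defaults
#' emulate the study design the analysis targets: a heavy-tailed (Zipf,
#' exponent 1.2) repertoire of 5,000 clones sampled at deep resolution
#' (1e5 templates) at the four blood timepoints, with two expansion events
#' at the post-cryoablation timepoint, both reverted afterwards: 20
#' mid-frequency clones (baseline frequency between 1e-3 and 1e-2) expanded
#' 4-fold, and the dominant clone (baseline >= 0.15) doubled — the
#' growth of the largest clones is what drives the transient clonality
#' (Simpson) peak, while the mid-frequency cohort is what a fold-change +
#' exact-test caller can recover individually. A five-analyte immune-marker
#' panel over 6 subjects accompanies the repertoire.
#'
#' @param nClones number of clones in the true repertoire.
#' @param abundanceModel `"zipf"` (rank exponent `zipfExponent`) or
#'   `"lognormal"` (`lnMeanlog`, `lnSdlog`).
#' @param zipfExponent,lnMeanlog,lnSdlog abundance-model parameters.
#' @param depth named integer vector, template totals per timepoint.
#' @param expansionSpec data.frame (`timepoint`, `nExpanded`, `fold`,
#'   `minBaseFreq`, `maxBaseFreq`); expansions multiply the true frequency
#'   of clones drawn from the stratum, then renormalize. Zero rows for a
#'   null simulation.
#' @param compartments compartment labels; the first carries the
#'   expansions (blood), the others share `sShare` of clone identities
#'   with it.
#' @param sShare shared-clone fraction for non-blood compartments.
#' @param perturbSdlog lognormal sd of compartment frequency perturbation.
#' @param nSubjects subjects for the analyte simulation.
#' @param analyteSpec see [defaultAnalyteSpec()].
#' @param seed mandatory integer seed; the same config and seed always
#'   produce byte-identical outputs.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nClones = 5000L,
                             abundanceModel = c("zipf", "lognormal"),
                             zipfExponent = 1.2,
                             lnMeanlog = 0, lnSdlog = 1.5,
                             depth = c(Pre = 1e5, PI = 1e5,
                                       PC = 1e5, PS = 1e5),
                             expansionSpec = data.frame(
                               timepoint = "PC",
                               nExpanded = c(20L, 1L),
                               fold = c(4, 2),
                               minBaseFreq = c(1e-3, 0.15),
                               maxBaseFreq = c(1e-2, 1),
                               stringsAsFactors = FALSE),
                             compartments = "blood",
                             sShare = 0.5,
                             perturbSdlog = 0.5,
                             nSubjects = 6L,
                             analyteSpec = defaultAnalyteSpec(),
                             seed) {
  if (missing(seed)) stop("a seed is mandatory; no wall-clock entropy")
  new("SimulationConfig",
      nClones = as.integer(nClones),
      abundanceModel = match.arg(abundanceModel),
      zipfExponent = zipfExponent, lnMeanlog = lnMeanlog,
      lnSdlog = lnSdlog,
      depth = stats::setNames(as.integer(depth), names(depth)),
      expansionSpec = expansionSpec,
      compartments = compartments, sShare = sShare,
      perturbSdlog = perturbSdlog,
      nSubjects = as.integer(nSubjects), analyteSpec = analyteSpec,
      seed = as.integer(seed))
}

# True baseline frequency vector under the configured abundance model,
# sorted descending so rank 1 is the most abundant clone.
.baselineFrequencies <- function(config) {
  n <- config@nClones
  w <- switch(config@abundanceModel,
    zipf = seq_len(n)^(-config@zipfExponent),
    lognormal = sort(stats::rlnorm(n, config@lnMeanlog, config@lnSdlog),
                     decreasing = TRUE))
  w / sum(w)
}

#' Simulate a longitudinal multi-compartment repertoire
#'
#' Draws true baseline clone frequencies from the configured abundance
#' model, injects the configured expansions on the true frequency vector
#' (biological expansion before sampling, then renormalization), and emits
#' per timepoint an observed clone table as a multinomial draw of the
#' configured depth — the sampling-noise model the expansion caller must
#' see through. Non-blood compartments share `sShare` of clone identities
#' with blood, with independently perturbed frequencies and no injected
#' expansions.
#'
#' @param config a valid [SimulationConfig-class].
#' @param patientId patient label stamped on the emitted tables.
#' @return list with `series` (named list of [SampleSeries-class], one per
#'   compartment) and `truth`: `baseline` (named true frequencies),
#'   `frequencies[[compartment]][[timepoint]]` (true post-injection
#'   frequencies), `expanded[[timepoint]]` (CDR3aa of injected clones).
#' @export
simulateSeries <- function(config, patientId = "SIM1") {
  validObject(config)
  set.seed(config@seed)
  base <- .baselineFrequencies(config)
  labels <- .randomCDR3(config@nClones)
  names(base) <- labels

  es <- config@expansionSpec
  tps <- names(config@depth)
  truthFreq <- list()
  expanded <- stats::setNames(vector("list", length(tps)), tps)
  bloodTruth <- lapply(tps, function(tp) {
    f <- base
    rows <- which(es$timepoint == tp)
    for (r in rows) {
      elig <- which(base >= es$minBaseFreq[r] & base <= es$maxBaseFreq[r])
      if (length(elig) < es$nExpanded[r])
        stop(sprintf(
          "stratum [%g, %g] holds %d clones; %d expansions requested",
          es$minBaseFreq[r], es$maxBaseFreq[r], length(elig),
          es$nExpanded[r]))
      sel <- sample(elig, es$nExpanded[r])
      f[sel] <- f[sel] * es$fold[r]
      expanded[[tp]] <<- sort(c(expanded[[tp]], labels[sel]))
    }
    f / sum(f)
  })
  names(bloodTruth) <- tps
  truthFreq[[config@compartments[1L]]] <- bloodTruth

  for (comp in config@compartments[-1L]) {
    nShared <- round(config@sShare * config@nClones)
    sharedIdx <- sort(sample(config@nClones, nShared))
    compLabels <- labels
    novel <- setdiff(seq_len(config@nClones), sharedIdx)
    if (length(novel))
      compLabels[novel] <- .randomCDR3(length(novel), exclude = labels)
    f <- base * stats::rlnorm(config@nClones, 0, config@perturbSdlog)
    f <- stats::setNames(f / sum(f), compLabels)
    truthFreq[[comp]] <- stats::setNames(
      rep(list(f), length(tps)), tps)
  }

  series <- lapply(config@compartments, function(comp) {
    tabs <- lapply(tps, function(tp) {
      f <- truthFreq[[comp]][[tp]]
      counts <- stats::rmultinom(1, config@depth[[tp]], f)[, 1L]
      names(counts) <- names(f)
      CloneTable(counts[counts > 0],
                 sampleId = paste(patientId, tp, comp, sep = "_"),
                 patientId = patientId, timepoint = tp,
                 compartment = comp)
    })
    names(tabs) <- tps
    SampleSeries(tabs, patientId = patientId)
  })
  names(series) <- config@compartments

  list(series = series,
       truth = list(baseline = base, frequencies = truthFreq,
                    expanded = expanded[!vapply(expanded, is.null,
                                                logical(1))]))
}

#' Simulate a subject x analyte x timepoint marker panel
#'
#' Per subject and analyte, draws a lognormal baseline level; the value at
#' each timepoint is `baseline * trueEffect * lognormal noise`. With zero
#' noise the baseline-relative log fold-change is exactly the log of the
#' true effect. Values falling below an analyte's declared LLOD stay in
#' the matrix as measured (censoring is applied at analysis time by
#' [logFoldChange()]); the LLOD metadata is attached.
#'
#' @param config a valid [SimulationConfig-class] with a non-empty
#'   `analyteSpec`.
#' @return list with `matrix` (an [AnalyteMatrix-class]) and `truth` (the
#'   analyte x timepoint matrix of true multiplicative effects).
#' @export
simulateAnalytes <- function(config) {
  validObject(config)
  spec <- config@analyteSpec
  if (nrow(spec) == 0L) stop("config has no analyteSpec")
  set.seed(config@seed + 1L)  # decoupled from the repertoire stream
  tps <- names(config@depth)
  subj <- sprintf("S%02d", seq_len(config@nSubjects))
  effCols <- paste0("effect.", tps)
  missing <- setdiff(effCols, names(spec))
  if (length(missing))
    stop("analyteSpec lacks columns ", paste(missing, collapse = ", "))
  eff <- as.matrix(spec[, effCols, drop = FALSE])
  dimnames(eff) <- list(spec$analyte, tps)

  arr <- array(NA_real_,
               dim = c(length(subj), nrow(spec), length(tps)),
               dimnames = list(subject = subj, analyte = spec$analyte,
                               timepoint = tps))
  for (a in seq_len(nrow(spec))) {
    baseLevel <- stats::rlnorm(length(subj), spec$baselineMeanlog[a],
                               spec$baselineSdlog[a])
    for (tp in seq_along(tps)) {
      noise <- if (spec$noiseSdlog[a] > 0)
        stats::rlnorm(length(subj), 0, spec$noiseSdlog[a]) else 1
      arr[, a, tp] <- baseLevel * eff[a, tp] * noise
    }
  }
  llod <- stats::setNames(as.numeric(spec$llod), spec$analyte)
  llod <- llod[!is.na(llod)]
  list(matrix = AnalyteMatrix(arr, llod = llod), truth = eff)
}

#' Subsample a clone table to a smaller depth
#'
#' Draws a smaller sample of templates from an observed clone table, for
#' deep-versus-survey resolution experiments. The default is a
#' without-replacement (multivariate hypergeometric) draw, so subsampling
#' to the full depth returns the table unchanged; `"multinomial"` draws
#' with replacement from the observed frequencies.
#'
#' @param table a valid [CloneTable-class].
#' @param depth target template total, `<= totalTemplates(table)`.
#' @param seed integer seed; the draw is deterministic per seed.
#' @param method `"hypergeometric"` (without replacement, default) or
#'   `"multinomial"`.
#' @return A [CloneTable-class] with the same metadata at the new depth.
#' @export
downsample <- function(table, depth, seed,
                       method = c("hypergeometric", "multinomial")) {
  stopifnot(is(table, "CloneTable"))
  method <- match.arg(method)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (depth > totalTemplates(table))
    stop("depth exceeds the table's template total")
  set.seed(as.integer(seed))
  counts <- cloneCounts(table)
  if (method == "multinomial") {
    sub <- stats::rmultinom(1, depth, counts / sum(counts))[, 1L]
  } else {
    # sequential conditioning: clone i gets rhyper draw from the balls
    # still in the urn
    sub <- integer(length(counts))
    remaining <- sum(counts)
    kLeft <- depth
    for (i in seq_along(counts)) {
      ni <- counts[[i]]
      x <- if (kLeft == 0L) 0L
           else stats::rhyper(1, ni, remaining - ni, kLeft)
      sub[i] <- x
      kLeft <- kLeft - x
      remaining <- remaining - ni
    }
  }
  names(sub) <- names(counts)
  CloneTable(sub[sub > 0], sampleId = sampleId(table),
             patientId = patientId(table), timepoint = timepoint(table),
             compartment = compartment(table),
             nDiscarded = discardedTally(table))
}
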