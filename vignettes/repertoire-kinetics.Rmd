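---
title: "Longitudinal TCR repertoire and immune-marker kinetics with repdyn"
author: "repdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal TCR repertoire and immune-marker kinetics with repdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repdyn)
```

## The problem

Immunotherapy trials that collect serial blood draws (and sometimes tissue)
ask three recurring questions of bulk TCRβ sequencing data: did the
repertoire become more *clonal* after treatment, which individual clones
*expanded* beyond what sampling noise can explain, and how do those clones
behave at later timepoints? Alongside the repertoire, gated flow-cytometry
populations and serum cytokine panels are followed as baseline-relative
kinetics. `repdyn` implements this analysis as a tested, seeded pipeline
operating on processed clone-abundance tables — the unit the sequencing
vendor actually delivers — plus subject × analyte × timepoint marker grids.

The canonical sampling schema is four blood draws: `Pre` (baseline, week
0), `PI` (post-immunotherapy, week 1), `PC` (post-cryoablation, week 2) and
`PS` (post-surgery, week 6). Tissue-site labels live in the same label
namespace, so multi-compartment designs need no special casing.

## Data model

A **clone** is a set of T cells sharing a CDR3 amino-acid sequence; that
string alone is the clone identity. Input rows carrying the same CDR3
amino acid (e.g. distinct nucleotide rearrangements) are aggregated by
summing template counts; V/J annotations, if present, are ignored. The
**productive filter** drops rows whose CDR3 is empty, contains a stop
(`*`) or undetermined (`X`) residue, or whose frame column — when the file
has one — is not in-frame; the discard tally is kept on the object.
Frequencies are always recomputed from post-filter counts and are never
trusted from the file.

`CloneTable` (one sample), `SampleSeries` (one patient's ordered tables),
`AnalyteMatrix` (marker grid with optional detection limits) and
`SimulationConfig` are S4 classes with validity methods, so malformed
objects fail at construction, not deep inside a statistic.

## Statistics

**Simpson clonality.** For clone frequencies $p_i$, the Simpson index is
$\sum_i p_i^2$ — the probability of drawing the same clone twice with
replacement. It is $1/K$ for a uniform repertoire of $K$ clones and 1 for
a monoclonal sample; higher means more clonal, less diverse. We report the
plug-in form on frequencies because its two-draw probability reading is
the definition used throughout; the without-replacement estimator
$\sum_i n_i(n_i-1)/(N(N-1))$ is available behind `unbiased = TRUE` but is
not the default. No rescaled "clonality score" (such as one minus
normalized entropy) is invented: raw Simpson is what is reported.

**Morisita–Horn overlap.** For two samples with frequencies $x_i, y_i$
over the clone union,
$$ M = \frac{2\sum_i x_i y_i}{\sum_i x_i^2 + \sum_i y_i^2}. $$
The denominator is the sum of the two Simpson indices; the factor 2 is
required for identical samples to score exactly 1, and disjoint samples
score exactly 0. The statistic is deliberately dominated by large clones —
replacing a low-frequency tail moves it very little — which is the
property that makes it robust to sequencing depth differences between
blood and tissue.

**Expansion calling.** A clone is *expanded* between a reference and a
comparison sample when its frequency increased by more than 2-fold **and**
the two-sided Fisher exact p-value of the 2×2 table
(clone templates, all other templates; per sample) is below 0.05. The
conjunction is the point: small clones fluctuate wildly in relative terms
but cannot reach significance, so the exact test filters sampling noise
while the fold criterion imposes effect size and direction. Choices the
caller fixes (and records in its output metadata):

* the 2×2 table is `(count, total − count)` per sample — the standard
  construction for repertoire frequency comparison;
* the test is two-sided; the fold criterion already imposes direction;
* raw p-values by default — the joint criterion is defined on the raw
  exact-test p — with Benjamini–Hochberg gating available via `bh = TRUE`;
* clones absent from the reference get fold-change `Inf` and stay eligible
  through the Fisher criterion alone; clones absent from the comparison
  are never expanded;
* no depth normalization between deep and survey resolution samples — the
  Fisher test conditions on the observed totals. `downsample()` exists for
  explicit resolution experiments but is never applied implicitly;
* the Fisher p-value is computed by direct enumeration of the
  hypergeometric support (exact, deterministic, no approximation), with
  the conventional `1 + 1e-7` relative tolerance when comparing table
  probabilities.

When driven from a `SampleSeries`, comparisons are later-vs-earlier; the
anchor pair defaults to `PC` vs `Pre` (the week-2 comparison) and is
recorded explicitly in every output, since tracking is only meaningful
relative to its anchor.

**Volcano and tracking.** `volcanoData()` lays calls out as log2
fold-change against −log10 p (capped for plotting; infinite or zero
fold-changes go to a sidecar rather than being dropped silently).
`trackExpanded()` takes the expanded set from the anchor comparison and
reports its summed frequency at every timepoint, 0 where a member is
absent.

**Marker kinetics.** Therapy effect per subject and analyte is the log
fold-change relative to baseline, $\log_b(v_t/v_{\text{Pre}})$ — base 10
for marker and cytokine summaries, base 2 where clone fold-changes are on
a log2 axis. Values below a declared lower limit of detection are floored
at the LLOD before the transform and the floored count is surfaced; zeros
with no declared LLOD become missing, never $-\infty$. Cell ratios
(e.g. CD8 over regulatory CD4, or CD8 over CD4⁺PD-1ʰⁱ) are elementwise
per subject with missing — not infinite — results at zero denominators.
Per-timepoint comparisons use the classical paired t test on complete
pairs; all-zero differences give $t = 0, p = 1$, while constant nonzero
differences are flagged degenerate with a missing p-value rather than a
fabricated 0. Cross-arm two-way ANOVA is out of scope here: it is an
off-the-shelf statistic applied downstream of these tables.

## The synthetic generator

Every stage is validated against a seeded generator
(`simulationConfig()`, `simulateSeries()`, `simulateAnalytes()`) rather
than against unavailable patient data, so its defaults state the study
conditions explicitly:

* **Abundance.** Zipf rank-frequency with exponent 1.2 over 5,000 clones —
  a heavy-tailed repertoire with a dominant clone near 20%, the structure
  seen in strongly clonal patients. A lognormal alternative is a config
  switch.
* **Sampling.** Each observed table is a multinomial draw of 10⁵ templates
  (deep resolution) from the true frequency vector; this is the noise
  model the expansion caller must see through. `downsample()` provides
  hypergeometric (without replacement) subsampling for survey-resolution
  experiments.
* **Expansions.** Injected on the *true* vector before sampling, then
  renormalized, so ground truth stays meaningful. The default injects, at
  `PC` only: 20 clones × 4-fold from the 10⁻³–10⁻² baseline-frequency
  stratum, plus the dominant clone (baseline ≥ 15%) × 2-fold. The split is
  deliberate: renormalization after expanding only mid-frequency clones
  *dilutes* the dominant clone and lowers $\sum p_i^2$, so a clonality
  peak at the expansion timepoint — the qualitative pattern the pipeline
  must reproduce — requires the largest clones themselves to grow, while
  the mid-frequency cohort is what a 2-fold/0.05 caller can recover
  clone-by-clone (their true post-renormalization fold is ≈ 3.4). The
  dominant clone's own true fold lands below 2, so it is intentionally
  not individually callable.
* **Compartments.** Non-blood compartments share a fraction `sShare`
  (default 0.5) of clone identities with blood, with lognormally perturbed
  frequencies (`perturbSdlog = 0.5`) and no injected expansions.
* **Analytes.** Five markers over 6 subjects: lognormal baselines,
  multiplicative true effects peaking at weeks 1–2 and reverting by week
  6, lognormal assay noise, declared LLODs for the cytokines. Zero-noise
  configs make log-FC exactly the log of the true effect, which pins the
  transform in tests.
* **Determinism.** The seed is mandatory; identical config + seed gives
  byte-identical emitted files. CDR3 labels are synthetic
  (`C` + 8–16 residues + `F`) so every fixture passes the productive
  filter.

What the generator does **not** emulate: V(D)J recombination statistics,
sequence-level errors, clone sharing through public clones, and
non-multinomial overdispersion between biological replicates. Passing
tests therefore demonstrate correctness of the statistics and calibration
under multinomial sampling — not that any particular patient cohort will
show these effect sizes.

## Numerical choices and degenerate inputs

* Frequencies must reconstruct counts/total to 1e-12 and sum to 1 within
  1e-9; violations are construction errors.
* Rank-frequency ties break lexicographically by CDR3 so outputs are
  byte-stable across runs; all tabular outputs are deterministic given
  identical inputs.
* Empty tables are invalid everywhere; operations report which
  precondition failed rather than emitting NaN.
* The self-overlap of any table is exactly 1 and the diagonal of an
  overlap matrix is set exactly, not via floating-point summation.
* Fisher p-values are never 0; −log10 p is capped only in the volcano
  export, never in the call table.

## Problem sizes used in the test-suite

The suite validates calibration at the generator's deep-resolution
defaults (5,000 clones, 10⁵ templates, 20 seeds for the type-I sweep,
1,000 replicates for the paired-t null), exhaustive Fisher enumeration for
all 2×2 margins up to 25 with a wide seeded sample up to margins of 200,
and a full two-run byte-identity check of the pipeline on the default
simulated fixture. These sizes were chosen so each property is measured
at the scale the analysis targets while a complete run stays desk-scale.

## A worked run

```{r, eval = FALSE}
cfg <- simulationConfig(seed = 11)
fx <- simulateToFiles(cfg, "fixtures")
conf <- list(
  seed = 11, outputDir = "out",
  samples = lapply(seq_len(nrow(fx$manifest)), function(i)
    as.list(fx$manifest[i, ])),
  comparisons = list(c("Pre", "PI"), c("Pre", "PC"), c("Pre", "PS")),
  tracking = list(ref = "Pre", cmp = "PC"),
  markers = list(path = fx$analytes, baseline = "Pre", base = 10,
                 llodPath = fx$llod))
report <- runPipeline(conf)
```

The output directory then holds `diversity.tsv`, `overlap.tsv` and
`overlap_matrix.tsv`, one `calls_*.tsv` per comparison, `tracked.tsv`,
`logfc.csv` and `report.json` (per-sample QC, thresholds, seed, and stage
status — including explicit `skipped` entries when a stage's inputs are
absent).

## Known limitations

* Clone identity is the CDR3 amino-acid string alone; analyses that need
  nucleotide-level lineage resolution are out of scope.
* Contraction is reported descriptively (fold-change < 1) but not tested
  for significance.
* The paired t path covers per-timepoint comparisons; multi-arm designs
  need an external ANOVA on the exported tables.
* Morisita overlap between samples of very unequal depth inherits the
  statistic's large-clone bias; that is a property, not a bug, but it
  should inform interpretation of blood-versus-tissue heatmaps.
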