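Package: repdyn
Title: Longitudinal T Cell Receptor Repertoire and Immune-Marker Kinetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of bulk T cell receptor (TCR)
    beta-chain repertoires and paired immune-marker panels. Reads processed
    clone-abundance tables (immunoSEQ-style TSV), aggregates clones by CDR3
    amino-acid sequence, and computes repertoire clonality (Simpson index),
    rank-frequency structure, and pairwise Morisita-Horn overlap. Calls
    significantly expanded clones between two samples using a joint
    fold-change and Fisher exact test criterion, exports volcano-plot data,
    and tracks expanded-clone sets across timepoints. Computes
    baseline-relative log fold-change kinetics, derived cell ratios, and
    paired t tests for flow-cytometry population frequencies and serum
    cytokine concentrations. A seeded synthetic-repertoire generator with
    multinomial sampling noise provides ground truth for validating every
    stage, and a single-configuration pipeline orchestrates the full
    analysis with a machine-readable run report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Sequencing, Immunology, StatisticalMethod, TimeCourse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'clone-io.R'
    'expansion.R'
    'markers.R'
    'pipeline.R'
    'repertoire-stats.R'
    'simulate.R'
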