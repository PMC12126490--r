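Package: ervscape
Title: Repeat-Family Enrichment, LTR Accessibility and Binding Biophysics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analyses of endogenous retroviral element (ERV)
    regulation: per-locus depth-normalized ChIP fold enrichment summarised to
    family medians and per-dataset z-scores with Spearman-rank hierarchical
    clustering; LTR deduplication, anchored coverage profiles and
    Wilcoxon/Benjamini-Hochberg differential-accessibility tests; genome-bin
    signal aggregation with Spearman correlation; and the accompanying
    biophysics: quadratic ligand-depletion binding isotherm fitting, NMR
    chemical shift perturbation metrics with peak matching, and half-bleach
    FRAP dip-depth readout. Includes synthetic-data generators emulating the
    statistical structure of every input so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bins.R'
    'biophys.R'
    'enrich.R'
    'ervscape-package.R'
    'io.R'
    'ltr.R'
    'synth.R'
    'utils.R'
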