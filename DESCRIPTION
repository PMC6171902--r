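Package: teratopd
Title: Quantal Tumorigenicity Assay Analysis for Pluripotent Stem Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for in vivo tumorigenicity (teratoma) assays
    of human pluripotent stem cell lines. Implements Spearman-Karber
    estimation of the 50% tumor-producing dose (TPD50) from quantal
    dose-incidence data, including the dummy-dose extension convention for
    series that do not span 0-100% incidence, with variance and normal-theory
    confidence intervals on the log10 scale. Also provides descriptive
    summaries of tumor volume, incidence and latency with tied rank ordering
    of cell lines; Kruskal-Wallis comparison of ordinal teratoma immaturity
    grades; a microarray probe-selection procedure (detection-call filter,
    per-line ANOVA filter, dual Spearman rank-correlation screen against
    latency and incidence); a cancer-gene variant-triage cascade over
    annotated exome variants (allele fraction, read depth, predicted impact,
    gene-list and COSMIC membership); and seeded synthetic-data generators
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
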