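Package: drugsynergy
Title: Drug-Combination Synergy Scoring and Downstream Genomic Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for two-drug combination studies in
    cell-based models: median-effect (Chou-Talalay) dose-response fitting
    and combination-index profiles for constant-ratio designs, the
    coefficient of drug interaction (CDI) with a replicate-level
    significance test, Bliss-independence excess scoring on dose matrices,
    a synergistic-gene-expression caller on four-condition expression
    tables with gene-set intersection and a genetic-dependence contrast,
    delta-Ct mRNA-decay half-life estimation from transcription-shutoff
    timecourses, and replicate-consensus interval analysis for ChIP peak
    sets (consensus calling, genome occupancy, promoter annotation and
    gene-level binding matrices). Includes seeded synthetic-data
    generators with recorded ground truth so every stage is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
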