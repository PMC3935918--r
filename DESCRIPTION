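Package: rnalifecycle
Title: mRNA Lifecycle Kinetics from a Single Total RNA-Seq Snapshot
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genome-wide pre-mRNA synthesis rates and the timescales of
    lariat formation, exon ligation, excised-intron degradation, and mRNA decay
    from a single strand-specific total RNA-Seq experiment. The steady-state
    model relates read densities over introns, splice sites, and exons to
    feature lifetimes; the declining read density along each intron gives a
    direct readout of relative synthesis rate. Includes gene-centric feature
    construction from transcript annotation, mappability-corrected density
    quantification, intron slope estimation with true-discovery-rate filtering,
    a Monte Carlo linear-system solver for the four processing times,
    meta-intron profile diagnostics, expression bimodality and gene-neighborhood
    analyses, and a synthetic-data generator with Poisson counting noise that
    serves as the test harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    mclust,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rsamtools,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
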