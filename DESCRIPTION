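Package: goosemethyl
Title: Whole-Genome Bisulfite Sequencing Differential Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for whole-genome bisulfite sequencing
    (WGBS) differential-methylation analysis between two groups (e.g. goose
    breeds across embryonic stages): binomial methylcytosine identification
    against an empirical non-CG false-positive background, CpG
    island/shore/shelf annotation, regional and metagene methylation
    profiling, 10-kb-window clustering and ordination, sliding-CpG-window
    differentially methylated region (DMR) detection with Fisher's exact
    test and Benjamini-Hochberg correction, differentially methylated gene
    calling, and integration with FPKM-classed expression into joint
    expression-by-methylation quadrants. Includes a synthetic-data module
    that generates a self-contained toy dataset (genome, gene models,
    methylomes for two breeds by three stages by three replicates,
    expression matrix, truth tables) with the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
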