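Package: chromcomp
Title: Chromosome-Scale Sequence Composition and Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-chromosome characterization of genome sequence composition
    (GC content, CpG density, observed/expected CpG ratio, CpG island
    calling), gene-cluster interval construction, chain-based liftOver with
    reciprocal filtering, SNP density and CpG-context classification of
    variants, conservation-track aggregation with acceleration flagging,
    CpG partitioning of inter-species substitutions from alignment blocks,
    expression dispersion summaries, and sperm-methylome style feature
    comparisons.  Includes a seeded synthetic-genome generator (first-order
    Markov sequences with calibrated CpG depletion, planted variants,
    substitutions, score tracks, chains and expression matrices) with
    machine-readable truth tables so every analysis stage is testable
    without external reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
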