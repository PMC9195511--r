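Package: nanocircle
Title: Detection of Extrachromosomal Circular DNA from Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects extrachromosomal circular DNA (eccDNA/ecDNA) from mapped
    long-read sequencing of circle-enriched libraries. Builds a directed
    breakpoint graph from read-depth change points and split reads, enumerates
    plausible circular paths through strongly connected components, emits
    candidates as VCF breakend chains, assigns each candidate a posterior
    probability under a binomial junction-support model, and reports annotated
    circles with junction sequences for primer design. Includes a nanopore-style
    read simulator and a recall/precision evaluator for benchmarking detection
    across coverage levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    VariantAnnotation,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
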