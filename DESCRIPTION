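Package: polymeth
Title: Comparative Methylome Analysis for Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative whole-genome bisulfite methylome analysis
    across diploid progenitors, interspecific hybrids, and allopolyploid
    species panels. Implements conserved-cytosine extraction from pairwise
    genome alignments, differentially methylated cytosine (DmC) and 100-bp
    window DMR calling with replicate ANOVA, methylation-divergence
    neighbor-joining phylogenetics with bootstrap support, gene-body
    methylation classification by binomial test together with Nei-Gojobori
    synonymous substitution rates for sequence-versus-epimutation comparison,
    homoeologous cDMR/hDMC classification tied to expression bias,
    hybrid-induced DMR maintenance analysis, and wild-versus-cultivated
    epiallele discovery. A synthetic methylome simulator with full ground
    truth supports end-to-end recovery benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    phangorn,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
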