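Package: ankfam
Title: Gene-Family Survey Toolkit for Ankyrin-Repeat Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reusable implementations of the computations behind a
    genome-wide survey of the ankyrin (ANK) repeat gene family: log-odds
    profile scanning for tandem ~33-residue repeats with empirical
    significance, domain-composition subfamily classification and censuses,
    chromosome mapping, gene-density clustering and exon/intron structure
    summaries from GFF3, duplication-pair detection by alignment coverage and
    identity, Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
    correction, selection classification and molecular dating, IUPAC
    cis-element scanning of promoter windows, RPKM and 2^-ddCt expression
    quantification, and seeded synthetic-data generators with planted truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    igraph,
    withr,
    stats,
    utils
Suggests:
    jsonlite,
    seqinr,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
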