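Package: lincforge
Title: Identification of Multi-Exon Intergenic Long Noncoding RNAs from
    Full-Length Transcript Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-stage pipeline for discovering intergenic long
    noncoding RNAs (lincRNAs) from genome-aligned full-length transcript
    models. Stages cover redundancy collapse of isoforms differing only at
    their 5'/3' ends, coding-potential scoring (ORF features, Fickett
    TESTCODE, in-frame hexamer usage bias, and a trainable logistic coding
    probability), protein/mRNA homology and domain filters, exon-chain
    comparison against a reference annotation with class codes, selection
    of multi-exon intergenic transcripts, RPKM quantification, count-based
    differential-expression screening between two libraries, and
    enrichment analysis of cis-target genes near lincRNA loci. A
    fully-labelled synthetic data generator provides planted-truth test
    beds for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rsamtools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
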