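Package: halomir
Title: Discovery and Salt-Stress Profiling of Plant MicroRNAs from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for annotating conserved and novel
    microRNAs in a plant transcriptome from small RNA sequencing libraries,
    built around the workflow used to profile halophyte seedlings under salt
    stress. Provides adapter trimming and read cleaning, collapsing to unique
    tags with size and 5'-nucleotide profiling, conserved-family assignment by
    near-exact matching to a mature miRNA reference with reads-per-million
    quantitation, hairpin precursor discovery on transcriptome contigs with a
    self-contained nearest-neighbour folding engine, a five-criterion duplex
    validity filter and MFE/AMFE/MFEI statistics, expectation-scored target
    prediction, degradome (PARE) t-plot cleavage confirmation, and
    delta-delta-Ct qPCR expression analysis. A synthetic-data generator with a
    machine-readable truth file makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
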