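Package: metarc
Title: Reference-Based Lossless Compression of Metagenomic Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless, reference-based compression and decompression of
    metagenomic FASTA/FASTQ read sets. Reads are classified against a
    taxonomy report, aligned to the genomes of the most abundant species,
    and stored as differences (start position, strand, base variations,
    paired-end offset) against those references; residual unaligned reads
    fall back to a reference-free 2-bit codec. Integer fields are entropy
    coded with canonical Huffman, Golomb, or extended Golomb codes, with
    distribution-fitting utilities (geometric, negative binomial, power
    law) to choose the codec and its divisor. Includes a synthetic
    metagenomic community simulator with ground-truth alignments and
    taxonomy reports, an iterative reference-discovery loop with pluggable
    aligner/assembler adapters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    MASS,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
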