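Package: microdrops
Title: Droplet Single-Microbe RNA-Seq Simulation, Demultiplexing and QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested toolkit for droplet-based high-throughput single-microbe
    RNA-seq data: split-pool bead barcode modelling and whitelist construction,
    Read1 demultiplexing with unique Hamming-distance-2 barcode correction, read
    to gene assignment and UMI deduplication into sparse count matrices with
    biotype accounting, knee-plus-EmptyDrops-like cell calling, barnyard
    (species-mixing), saturation and gene-body-coverage quality metrics, and
    Cas9 guide design for CRISPR-based depletion of rRNA-derived cDNA with
    in-silico digestion. A read-level simulator emulating the library chemistry
    (random-primer capture with 5' bias, Poisson droplet co-encapsulation,
    rRNA-dominated biotype composition, barcode sequencing errors) provides
    ground truth so that every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
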