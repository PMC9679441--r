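Package: coipipe
Title: COI Metabarcoding Pipeline with Abundance-Aware Single-Mismatch OTU
    Clustering and GMYC Species Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for cytochrome c oxidase subunit 1 (COI) amplicon
    metabarcoding of bulk community samples. Implements demultiplexing of
    inline octanucleotide sample tags, quality filtering, IUPAC-aware primer
    trimming, paired-end read merging and fixed-length (313 bp) selection;
    dereplication at 100% identity followed by abundance-aware merging of
    unique sequences that differ by a single nucleotide into operational
    taxonomic units (OTUs); single-threshold Generalised Mixed Yule
    Coalescent (GMYC) species delimitation on ultrametric trees; and
    percent-identity taxonomy assignment from tabular best-hit files.
    Includes simulators for mock-community paired reads and
    Yule-over-coalescent gene trees with known species membership, so every
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
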