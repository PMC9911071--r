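Package: shatterscan
Title: Detection and Characterization of Chromoanagenesis from Short-Read Dosage,
    Junction, and Haplotype Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterize a shattered, randomly reassembled
    chromosome (chromoanagenesis/chromothripsis) in short-read resequencing data of
    an individual plant, such as a trisomic Arabidopsis offspring of defective
    meiosis. Implements binned read-dosage normalization against diploid controls
    on the diploid-equals-2 scale, discovery of novel DNA junctions from
    distant-mate read pairs with control subtraction and support filtering, local
    contig assembly with exact-anchor breakpoint resolution and repair-class
    calling (microhomology, perfect, insertion), chaining of junctions into
    reconstructed rearranged fragments, parental-haplotype dosage analysis
    distinguishing meiosis-I from meiosis-II mis-segregation, and permutation
    tests for breakpoint enrichment in annotation tracks. A fully seeded
    synthetic-data generator produces shattered chromosomes, offspring karyotypes,
    reads, and idealized alignments with complete ground truth so every stage is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
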