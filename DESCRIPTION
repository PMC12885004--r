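Package: TeloCentR
Title: Telomere, Centromere and Retroelement Characterization of Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-assembly characterization of telomere-to-telomere genome
    assemblies: scanning chromosome ends for high-copy tandem repeats with
    exact repeat counting and noncanonical motif discovery, genome-wide
    satellite-array detection and clustering for centromere calling,
    six-frame translation and protein-domain scanning of LTR
    retrotransposons, and one-tailed Fisher exact tests for domain
    enrichment in centromeric versus noncentromeric partitions. Includes a
    synthetic-assembly simulator that plants telomeric arrays, centromeric
    satellite regions, domain-bearing LTR elements and genes with full
    truth tables, plus assembly summary statistics (N50) and windowed
    GC/gene-density tracks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
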