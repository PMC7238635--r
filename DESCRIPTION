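Package: gapless
Title: Optical-Map-Anchored Merging of Long-Read Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconciles two independent long-read contig assemblies into
    gapless chromosome-scale pseudomolecules using consensus optical maps
    as the anchoring evidence. Implements in-silico digestion and a
    dynamic-programming label-map aligner with rescaling, map-vs-sequence
    conflict detection and chimeric-contig cutting, insertion/deletion
    error curation by cross-assembly patching, k-mer anchored overlap
    detection and unitig merging, hybrid scaffolding with map-estimated
    gap sizes and the 13N overlap convention, iterative long-read gap
    filling, telomere extension, and genetic-map-driven pseudomolecule
    construction (AGP). Also provides rule-based annotation of tandem
    repeat arrays (satellite knobs and centromeric repeats), k-mer
    uniqueness (effective genome size), mappability islands, CENH3
    ChIP-seq enrichment island calling, RPKM enrichment ratios, and
    interval co-occurrence tests, together with a truth-annotated
    synthetic genome/assembly/optical-map simulator used for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
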