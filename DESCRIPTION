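Package: tripnseq
Title: Mapping Transcription-Replication Interactions from TRIPn-Seq Fragment Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies transcription-replication interaction (TRI) loci from
    replicate TRIPn-Seq fragment data (sequential RNAP2s5 / BrdU
    immunoprecipitation) by combining candidate peak calling, a replicate-aware
    beta-binomial differential enrichment test with Benjamini-Hochberg FDR
    control, and a sliding-window scan around transcription start sites.
    Called loci are characterized with replication fork directionality from
    Okazaki-fragment strand counts, replication-timing log2 ratios, GC skew and
    GC content, G-quadruplex propensity scoring, transcription-orientation
    classification, metagene profile aggregation, randomization-based overlap
    statistics, and region-level variant enrichment. A deterministic
    synthetic-data generator plants ground-truth loci so that every stage of
    the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0)
biocViews: Sequencing, ChIPSeq, Coverage, PeakDetection, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
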