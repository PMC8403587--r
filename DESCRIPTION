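Package: bgcfam
Title: Biosynthetic Gene Cluster Mining and Gene Cluster Family Networking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects biosynthetic core genes in annotated fungal genomes by
    Smith-Waterman template search, assembles biosynthetic gene cluster (BGC)
    loci around them with a three-consecutive-unrelated-genes border rule,
    assigns each locus to a biosynthetic class taxonomy (PKS subtypes, NRPS and
    NRPS-like, hybrids, terpenes, alkyl citrates, alkaloids, RiPPs), groups BGCs
    into gene cluster families (GCFs) with a weighted Jaccard / domain sequence
    identity / adjacency similarity distance, and compares clusters by
    best-link synteny and co-localised homolog search. Ships a synthetic-cohort
    generator that plants ground-truth clusters in simulated genomes so every
    pipeline stage can be validated against a known answer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
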