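Package: sescreen
Title: Super-Enhancer Screening and Integrative Dependency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for super-enhancer screening in
    cancer epigenomics, modeled on the Ewing sarcoma setting. Calls
    super-enhancers from H3K27Ac ChIP-seq peaks and signal tracks by
    ROSE-style stitching and rank-cutoff classification, assigns
    transcriptionally active genes to enhancers within a distance window,
    scans genome sequence for GGAA microsatellites and quantifies their
    enrichment (and that of EWS/FLI1 binding peaks) at super-enhancers,
    builds metagene signal profiles, computes gene-set enrichment with a
    permutation null, and intersects super-enhancer genes with
    shRNA-dependency (signal-to-noise selectivity) and drug-sensitivity
    (Mann-Whitney) screens. Includes a fully seeded synthetic-data
    generator that emulates the statistical structure of such studies so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
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
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, Epigenetics, GeneRegulation, FunctionalGenomics,
    GeneSetEnrichment, Software
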