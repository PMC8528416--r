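Package: enhancerCircuits
Title: Super-Enhancer Landscapes and Core Regulatory Circuitry from
    Binned Chromatin Coverage
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing enhancer landscapes and core
    regulatory circuitry (CRC) from ChIP-seq and CUT&RUN style coverage
    data. Builds 50-bp binned, reads-per-million normalized coverage
    tracks from aligned read positions; calls and collapses peak sets;
    identifies super-enhancers by ROSE-style stitching and the
    hockey-stick tangent cutoff; assigns enhancers to expressed genes by
    promoter activity and TSS proximity; quantifies differential H3K27ac
    enrichment across conditions over a collapsed super-enhancer union;
    builds transcription-factor co-occupancy matrices and infers
    interconnected autoregulatory CRC membership; and normalizes
    expression count tables with ERCC spike-in size factors so that
    global transcriptome shifts remain identifiable. A seeded synthetic
    data generator plants enhancers, CRC wiring and expression shifts
    with a ground-truth manifest so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse,
    knitr
biocViews: ChIPSeq, Epigenetics, GeneRegulation, Transcription,
    Coverage, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
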