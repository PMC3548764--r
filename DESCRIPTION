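Package: svfuse
Title: Structural Variant Discovery and Fusion Gene Prediction from
    Discordant Read Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers genomic rearrangement junctions from discordant
    paired-end read alignments and predicts expressed fusion genes.
    Implements mapping-quality and PCR-duplicate filtering of read pairs,
    geometric clustering of discordant pairs into junction candidates, a
    filter cascade (minimum span, copy-number-variant blacklist, panel of
    normals), confirmation of candidates against copy-number steps from
    segmented array-CGH-like probe profiles, orientation-aware prediction
    of direct and run-through fusion transcripts with reading-frame calls,
    junction microhomology and genomic-shard characterisation, and
    physical-coverage, Poisson-detection and capture-recapture estimators.
    A seeded simulator generates toy genomes, gene models, planted
    rearrangements (including high-copy coamplifications), read-pair
    libraries with PCR-duplicate and coligation artifacts, and noisy
    copy-number probe profiles, so the whole pipeline can be exercised
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
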