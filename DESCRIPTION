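Package: svpopscan
Title: Multi-Caller Structural Variant Consensus and Population Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a consensus structural-variant (SV) map from multiple
    callers' VCF call sets by reciprocal-overlap clustering, a two-or-more
    caller support rule and median breakpoints; derives per-sample consensus
    genotypes and per-population allele frequencies; scans biallelic deletions
    for selection signatures with the absolute allele-frequency difference
    (dAF) and the relative frequency difference (RFD), flagging sites in the
    empirical top 5 percent of both statistics; aggregates significant sites
    into regions and annotates SVs and regions against gene models. Includes
    a synthetic-data generator that emulates multi-caller call sets over
    structured populations (breakpoint jitter, false positives and negatives,
    Hardy-Weinberg genotypes, planted selected deletions) so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
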