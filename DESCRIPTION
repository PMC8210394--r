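Package: hapmark
Title: Histone-Mark Enrichment and TAD Gene Mapping for Disease Risk Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores enrichment of histone-mark ChIP-seq peaks (H3K4me1,
    H3K27ac, H3K9ac) within disease-associated linkage-disequilibrium (LD)
    blocks against an empirical null of matched-length random genomic
    regions, maps marked blocks to topologically associated domains (TADs),
    enumerates the genes within those TADs, and cross-references them with
    differential-expression gene lists from tissue studies. Ships the 16
    intracranial-aneurysm risk LD blocks and the published tissue DEG
    records as plain-text fixtures, and a seeded synthetic-data generator
    (toy genome, blocks, peak sets with planted enrichment, TAD partitions,
    gene models, DEG tables) with recorded ground truth so the whole
    pipeline is testable and calibratable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
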