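Package: mirconserve
Title: Conservation Scoring of Human miRNAs from Population Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies within-human-population conservation of mature
    microRNAs from allele-frequency data. Four component scores -- seed
    conservation (SCS), non-seed conservation (NSCS), positional coverage
    (PCS) and total variant burden (TVS) -- are combined into a weighted
    Overall Conservation Score (OCS). The component weights can be
    optimized over a constrained grid against the overlap between highly
    conserved and highly expressed miRNAs (F1 / z-score selection).
    Additional tools classify variants by allele-frequency class,
    transition/transversion type and ref:alt RNA pair, profile variant
    density by hairpin region (with 2-nt 3' overhang arm inference),
    detect compensatory miRNA-target variant pairs that preserve seed
    base-pairing in 3'UTR binding sites (6mer/7mer-A1/7mer-m8/8mer),
    and run the downstream statistics (permutation, Fisher, rank-based
    tests, APA-related ratios, confidence-coverage curves). A seeded
    synthetic-fixture generator with planted ground truth makes every
    analysis testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
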