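Package: mutmapr
Title: Bulked-Segregant SNP-Index Mapping of EMS Mutants with a Forward
    Cross Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the improved-MutMap strategy for mapping the causal
    gene of a recessive EMS-induced mutant: a forward simulator of the
    mutant x wild-type F2 cross with phenotype-selected sequencing bulks,
    per-SNP and sliding-window SNP-index statistics for both bulks,
    candidate-region detection, a dual-bulk causal-SNP filter (mutant-bulk
    index 1, wild-type-bulk index near 1/3 for a monogenic recessive), and
    strand-aware coding-effect annotation of candidate variants against
    gene models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
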