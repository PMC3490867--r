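Package: polymirts
Title: Polymorphic miRNA Target Site Discovery from RNA-Seq Variants
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts microRNA target sites on reference and variant 3'-UTR
    alleles under three complementary criteria (canonical seed match with a
    local-context score, seed match with site accessibility and
    over-representation ranking, and non-canonical 3'-compensatory pairing),
    classifies polymorphic target sites as created, disrupted or perturbed,
    filters candidate SNPs by call quality, read depth, 3'-UTR coverage and
    k-mer genome mappability, and tests miRNA/target co-expression and
    allele-specific expression with exact tests. Ships seeded synthetic-data
    generators with planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    methods,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
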