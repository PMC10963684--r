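Package: haplomine
Title: Gene-Based Haplotype Candidate Mining for QTL Regions
Version: 0.1.0
Authors@R:
    person("Haplomine", "Developers", email = "haplomine@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing candidate genes inside a QTL interval by
    gene-based haplotype analysis in inbred diversity panels. Delimits the
    candidate region from pairwise linkage disequilibrium around an
    association peak, enumerates per-gene haplotypes from promoter and CDS
    variants (SNPs, InDels and presence/absence variants), filters to major
    haplotypes, and tests phenotype differences among haplotypes across
    cultivation environments with one-way ANOVA and Duncan's multiple range
    test (compact letter displays, raw-data and summary-statistics modes).
    Includes two-gene haplotype-combination (pyramiding) dominance screening,
    trait correlation, knockout percent-reduction effect computation, and a
    seeded synthetic panel generator for power and type-I-error checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Rsamtools,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
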