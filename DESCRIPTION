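Package: peakgwas
Title: Linking Transcription-Factor Binding Regions to GWAS Disease Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating transcription-factor ChIP-seq binding
    regions with genome-wide association study (GWAS) results. Implements
    consolidation of replicate antibody peak sets by a containment-aware
    intersection rule, nearest-TSS target-gene assignment within a fixed
    window, overlap enrichment against open-chromatin backgrounds,
    LD-pruned functional-SNP enrichment of low GWAS P-values (Fisher and
    one-sided Kolmogorov-Smirnov tests), matched-size permutation
    enrichment of trait gene sets against an all-GWAS-gene background,
    and an average-max-r2 linkage-disequilibrium pairing statistic with
    an empirical trait-label permutation null. A seeded synthetic-data
    generator emulates LD-block variant panels, trait catalogs and GWAS
    summary statistics so every stage can be exercised end-to-end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
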