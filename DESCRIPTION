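Package: sdscan
Title: Discovery of Sex-Determination Loci from Pooled-Sex Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping master sex-determination genes from
    pooled-sex whole-genome sequencing of fishes. Classifies variant
    sites from multi-sample VCFs against three XX/XY pooled-genotype
    models (Y-specific allele, X-null locus, Y-null locus), retains
    sites concordant across species, detects male-specific genomic
    intervals from per-pool depth tracks, performs electronic PCR
    (exact-word probe detection with RPKM summaries) against read
    libraries, validates exon/intron gene models and primer amplicon
    arithmetic, tests genotype-by-sex association with Fisher's exact
    test, and checks species identity with cox1 barcode p-distances.
    Includes seeded generators for synthetic VCFs, depth tracks, read
    libraries and family tables so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    vcfR,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
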