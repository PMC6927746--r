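Package: wildiso
Title: Population Genomics and Field Ecology of Selfing Wild Isolates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream population-genomic and field-ecology analysis of
    wild isolates of selfing nematodes. Loads multi-sample VCFs, applies
    per-call and per-site quality filters, deduplicates isolates into
    isotypes (genome-wide haplotypes) by pairwise SNV concordance,
    computes sliding-window nucleotide diversity, Watterson's theta,
    Tajima's D and Hudson's F_ST among isotypes, infers haplotype
    structure from identity-by-descent segments and classifies
    chromosomes as carrying the globally swept haplotype, and analyses
    geo-referenced field-collection records (substrate enrichment,
    geographic clustering, environmental comparisons). A seeded
    synthetic-data generator produces genotype matrices, IBD ground
    truth, and collection tables with the statistical structure the
    analysis assumes, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    geosphere,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
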