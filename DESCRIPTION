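Package: wgva
Title: Whole-Genome Variant Association for Breed-Defining Recessive Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for case/control whole-genome variant
    association screens of breed-defining recessive traits in structured
    populations, modelled on the canine screw-tail mapping design. Covers
    GATK-style site-level hard filtering and indel recoding, cohort QC
    (missingness and minor-allele-frequency filters, identity-by-state
    distances and dendrograms, variance-inflation-factor LD pruning, trio
    Mendelian-error audits), allelic chi-square association with genomic
    control and pruned-haplotype Bonferroni correction, an allele-frequency
    fixation scan that assembles candidate regions, segregation and penetrance
    tables with exact tests, and a transcript-level frameshift consequence
    caller. A breed-structured synthetic cohort generator (Balding-Nichols
    allele frequencies, Hardy-Weinberg genotypes, linkage-disequilibrium
    blocks, trios, missingness and site annotations) makes every stage
    testable without access to real genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
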