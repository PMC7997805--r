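Package: cypstar
Title: CYP2D6 Star-Allele Diplotyping from Whole-Genome Sequencing Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Genotypes the pharmacogene CYP2D6 from short-read whole-genome
    sequencing despite its near-identical pseudogene paralog CYP2D7. The
    combined CYP2D6+CYP2D7 copy number and the copy number of the unique
    spacer region are called from GC-corrected normalized depth with a
    Gaussian mixture model; reads are apportioned between the paralogs at a
    panel of 117 reliable differentiating bases with a binomial likelihood to
    detect deletions, duplications and CYP2D6/CYP2D7 hybrid genes;
    star-allele-defining small variants are genotyped with paralog-aware
    read pooling; and a consistent star-allele diplotype is resolved by
    exact-cover search with CPIC activity-score phenotype translation.
    Includes cohort utilities (trio consistency, haplotype frequencies,
    truth-set concordance) and a seeded simulator that generates counts-level
    evidence or miniature BAM files for any modelled diplotype.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
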