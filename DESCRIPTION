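Package: exomerescue
Title: Reanalysis Toolkit for Unsolved Clinical Trio Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reanalysis workflow for clinical exome cases that remained
    molecularly undiagnosed after a first singleton pass. Implements de novo
    variant detection by in-silico parental subtraction with allelic-depth
    criteria, a stepwise Mendelian inheritance-model filtering workflow
    (autosomal-recessive homozygous, compound heterozygous with trans phasing
    from parental genotypes, heterozygous loss-of-function, de novo and
    X-linked hemizygous), exact binomial testing for low-level parental
    mosaicism, B-allele-frequency based absence-of-heterozygosity segmentation
    with whole-chromosome uniparental-disomy flagging and parental-origin
    inference, single-exon dropout deletion calling from normalized per-exon
    coverage, a cohort-wide rare homozygous stop-gain gene scan, and
    diagnostic-yield reporting with a combined-yield projection. Includes a
    synthetic trio-cohort generator (VCF + PED + exon coverage + truth table)
    so every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
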