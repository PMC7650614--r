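Package: karyotag
Title: Molecular Inversion Karyotyping from SNP Data and Tag-SNP Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotyping polymorphic chromosomal inversions in
    mosquito cohorts without cytogenetics. Imputes inversion genotypes
    from SNP variation by principal component analysis restricted to the
    inversion's breakpoint span, anchored on a subset of cytogenetically
    karyotyped specimens; ascertains tag SNPs whose alternate-allele dose
    tracks inversion orientation; genotypes specimens from allele-specific
    amplicon read counts or pre-called tag genotype matrices; averages and
    bins tag genotypes into multilocus inversion calls; and summarises
    concordance among cytogenetic, PCA and molecular genotyping methods.
    Includes a synthetic-cohort simulator with full truth tables so the
    whole pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
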