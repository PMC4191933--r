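Package: cehtools
Title: Conserved Extended Haplotype Architecture Analysis in the MHC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the architecture of conserved extended
    haplotypes (CEHs) in the human MHC class II region from pedigree-phased
    marker data. Reconstructs founder haplotypes by segregation analysis in
    nuclear pedigrees, assigns haplotypes to CEH groups by core-marker
    alleles, derives each group's dominant (consensus) sequence with
    tolerance for isolated private variation, traces sequence-fixity curves,
    localizes crossover break points to marker intervals, measures how far
    an external reference haplotype represents a group, detects regional tag
    markers and private variants, and computes the normalized crossover
    frequency (NCF) statistic per genomic sub-region. Includes a synthetic
    cohort generator that plants ancestral haplotypes, recombination with
    background haplotypes, private mutations, amplicon-level missingness and
    pedigree transmission, together with a ground-truth ledger for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
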