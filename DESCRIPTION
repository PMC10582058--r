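Package: imprintscan
Title: Discovery of Imprinted Genes from Phased Methylation and Allelic Expression
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for discovering genomically imprinted
    loci in outbred mammalian cohorts. Phases heterozygous SNPs from long
    reads by greedy minimum-error-correction, assigns methylation-bearing
    reads to haplotypes, calls allele-specific methylation (ASM) sites with
    exact per-CpG tests, screens per-SNP allelic RNA counts for monoallelic
    expression (Fisher exact against 1:1, Bonferroni corrected), links
    candidates to ASM within 1 Mb, assigns parent of origin from
    mother-offspring duos, quantifies germline methylation reprogramming
    (erasure and re-establishment in primordial germ cells, sperm
    concordance), and computes cohort heterozygosity (sMLH) and a
    weaning-signature expression screen. Ships a fully seeded synthetic
    diploid cohort generator with machine-readable truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stats,
    generics,
    ggplot2,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
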