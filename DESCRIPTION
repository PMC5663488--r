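Package: hlaassoc
Title: Case-Control Association Analysis for HLA Alleles, Haplotypes and
    Amino-Acid Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for HLA case-control association studies at two-field
    allele resolution: carrier-frequency tests under the dominant model with
    exact two-sided 2x2 inference, odds ratios with a conditional
    Haldane-Anscombe zero-cell correction and Woolf confidence intervals,
    allele-level Bonferroni correction, serological grouping and shared-epitope
    classification of DRB1 alleles, DRB1-DQB1 haplotype phasing by direct
    counting under strong linkage disequilibrium, genotype- and
    diplotype-class scans, amino-acid residue fine mapping of the DRbeta and
    DQbeta chains, cis/trans DQ alpha-beta heterodimer enumeration, and a
    synthetic two-locus cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
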