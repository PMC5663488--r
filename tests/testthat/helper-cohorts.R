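# shared fixtures built in code

# a genotype tibble from allele pairs given as bare two-field names
make_cohort <- function(status, drb1, dqb1 = NULL, ...) {
  n <- length(status)
  out <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    status = status,
    DRB1_1 = hla_allele(vapply(drb1, `[`, "", 1), locus = "DRB1",
                        quiet = TRUE),
    DRB1_2 = hla_allele(vapply(drb1, `[`, "", 2), locus = "DRB1",
                        quiet = TRUE))
  if (!is.null(dqb1)) {
    out$DQB1_1 <- hla_allele(vapply(dqb1, `[`, "", 1), locus = "DQB1",
                             quiet = TRUE)
    out$DQB1_2 <- hla_allele(vapply(dqb1, `[`, "", 2), locus = "DQB1",
                             quiet = TRUE)
  }
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# brute-force two-sided Fisher P: enumerate every table with the observed
# margins from binomial coefficients (independent of dhyper)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(N, c1))
  sum(pr[pr <= pr[ks == a] * (1 + 1e-7)])
}

# the bundled six-haplotype control catalog backing the simulation tests
control_hap_config <- function(n_cases, n_controls, ...) {
  counts <- read_counts(hla_example("drb1_dqb1_haplotype_counts.tsv"))
  config_from_counts(counts[counts$kind == "haplotype", ],
                     n_cases = n_cases, n_controls = n_controls, ...)
}

# does an assignment pair match the simulated truth (order-free)?
phase_matches_truth <- function(phasing, cohort) {
  truth <- attr(cohort, "truth")
  asg <- phasing$assignments[match(truth$sample_id,
                                   phasing$assignments$sample_id), ]
  ok <- (asg$hap1 == truth$hap1 & asg$hap2 == truth$hap2) |
    (asg$hap1 == truth$hap2 & asg$hap2 == truth$hap1)
  ok[is.na(ok)] <- FALSE
  ok
}
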