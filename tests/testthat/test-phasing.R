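test_that("samples homozygous at either locus phase uniquely", {
  g <- make_cohort(
    status = c("case", "case"),
    drb1 = list(c("04:05", "04:05"), c("04:05", "08:03")),
    dqb1 = list(c("04:01", "04:01"), c("04:01", "04:01")))
  ph <- phase_cohort(g)
  expect_equal(ph$n_ambiguous, 0)
  expect_equal(sort(c(ph$assignments$hap1[1], ph$assignments$hap2[1])),
               rep("DRB1*04:05-DQB1*04:01", 2))
  expect_setequal(c(ph$assignments$hap1[2], ph$assignments$hap2[2]),
                  c("DRB1*04:05-DQB1*04:01", "DRB1*08:03-DQB1*04:01"))
  expect_error(phase_cohort(make_cohort("case",
                                        list(c("04:05", "08:03")))),
               "both loci")
})

test_that("doubly heterozygous samples follow the frequency rule", {
  # unambiguous pool carrying H1 = 04:05-04:01 (common), H2 = 08:03-06:01,
  # H3 = 13:02-06:04; one double-het resolvable sample
  pool_haps <- c(rep("04:05|04:01", 30), rep("08:03|06:01", 14),
                 rep("13:02|06:04", 6))
  drb1 <- lapply(strsplit(pool_haps, "|", fixed = TRUE), function(h) {
    c(h[1], h[1])
  })
  dqb1 <- lapply(strsplit(pool_haps, "|", fixed = TRUE), function(h) {
    c(h[2], h[2])
  })
  g <- make_cohort(status = rep("control", 50), drb1 = drb1, dqb1 = dqb1)
  amb <- make_cohort(status = "control",
                     drb1 = list(c("04:05", "08:03")),
                     dqb1 = list(c("04:01", "06:01")))
  amb$sample_id <- "AMB"
  ph <- phase_cohort(dplyr::bind_rows(g, amb))
  # freq(H1)*freq(H2) = 60*28 beats the swapped pairing (unseen haplotypes)
  row <- ph$assignments[ph$assignments$sample_id == "AMB", ]
  expect_false(row$ambiguous)
  expect_setequal(c(row$hap1, row$hap2),
                  c("DRB1*04:05-DQB1*04:01", "DRB1*08:03-DQB1*06:01"))
})

test_that("a catalog resolves double heterozygotes and ties are flagged", {
  catalog <- tibble::tibble(drb1 = c("04:05", "08:02"),
                            dqb1 = c("04:01", "03:02"))
  lone <- make_cohort(status = "case",
                      drb1 = list(c("04:05", "08:02")),
                      dqb1 = list(c("04:01", "03:02")))
  ph <- phase_cohort(lone, catalog = catalog)
  expect_equal(ph$n_ambiguous, 0)
  expect_setequal(c(ph$assignments$hap1, ph$assignments$hap2),
                  c("DRB1*04:05-DQB1*04:01", "DRB1*08:02-DQB1*03:02"))
  # without any information the same sample is an exact tie
  ph2 <- phase_cohort(lone)
  expect_equal(ph2$n_ambiguous, 1)
  expect_true(is.na(ph2$assignments$hap1))
  expect_equal(nrow(ph2$frequencies), 0)
})

test_that("phasing conserves the input allele multisets", {
  cfg <- control_hap_config(150, 150)
  g <- sample_cohort(cfg, seed = 9)
  ph <- phase_cohort(g)
  asg <- ph$assignments[!ph$assignments$ambiguous, ]
  gg <- g[match(asg$sample_id, g$sample_id), ]
  drb_back <- cbind(sub("-.*$", "", asg$hap1), sub("-.*$", "", asg$hap2))
  dqb_back <- cbind(sub("^.*-", "", asg$hap1), sub("^.*-", "", asg$hap2))
  for (i in seq_len(nrow(asg))) {
    expect_setequal(drb_back[i, ], c(gg$DRB1_1[i], gg$DRB1_2[i]))
    expect_setequal(dqb_back[i, ], c(gg$DQB1_1[i], gg$DQB1_2[i]))
  }
  # frequencies: 2 * phased samples copies, summing to 1
  expect_equal(sum(ph$frequencies$count),
               2 * (ph$n_samples - ph$n_ambiguous))
  expect_equal(sum(ph$frequencies$freq), 1)
})

test_that("phasing recovers simulated truth under strong LD", {
  cfg <- control_hap_config(250, 250)
  hit <- unlist(lapply(1:4, function(s) {
    coh <- sample_cohort(cfg, seed = 100 + s)
    phase_matches_truth(phase_cohort(coh), coh)
  }))
  expect_gte(mean(hit), 0.99)
})

test_that("haplotype and diplotype scans reproduce published statistics
          from count fixtures", {
  counts <- read_counts(hla_example("drb1_dqb1_haplotype_counts.tsv"))
  res <- assoc_test(counts)
  or_of <- function(u) round(res$or[res$unit == u], 2)
  expect_equal(or_of("DRB1*04:05-DQB1*04:01"), 4.32)
  expect_equal(or_of("DRB1*04:01-DQB1*03:01"), 4.42)
  expect_equal(or_of("DRB1*04:05-DQB1*04:01/DRB1*08:02-DQB1*03:02"), 24.77)
  expect_equal(or_of("DRB1*04:05-DQB1*04:01/DRB1*08:03-DQB1*06:01"), 10.64)
})

test_that("haplotype and diplotype scans work end-to-end on phased cohorts", {
  cfg <- control_hap_config(200, 200)
  g <- sample_cohort(cfg, seed = 21)
  ph <- phase_cohort(g)
  hres <- haplotype_carrier_scan(ph)
  expect_s3_class(hres, "hla_assoc")
  expect_true(all(hres$case_total <= 200))
  # absent haplotype: corrected OR 1, P 1
  none <- haplotype_carrier_scan(ph, units = "DRB1*03:01-DQB1*05:01")
  expect_equal(none$or, 1); expect_equal(none$p, 1)
  dres <- diplotype_scan(ph, c(
    "DRB1*04:05-DQB1*04:01/DRB1*04:05-DQB1*04:01",
    "DRB1*04:05-DQB1*04:01/not",
    "DRB1*03:01-DQB1*05:01/DRB1*03:01-DQB1*05:01"))
  expect_equal(nrow(dres), 3)
  expect_equal(dres$p[3], 1)
  # carriers = homozygotes + heterozygous carriers
  hap_carriers <- hres$case_carriers[
    hres$unit == "DRB1*04:05-DQB1*04:01"]
  expect_equal(dres$case_carriers[1] + dres$case_carriers[2], hap_carriers)
})
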