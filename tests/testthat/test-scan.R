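test_that("carrier scan counts homozygotes once and matches aggregation", {
  g <- make_cohort(
    status = c("case", "case", "case", "control", "control"),
    drb1 = list(c("04:05", "04:05"), c("04:05", "08:03"),
                c("13:02", "15:01"), c("04:05", "13:02"),
                c("09:01", "09:01")))
  counts <- carrier_counts(g, "DRB1")
  r <- counts[counts$unit == "DRB1*04:05", ]
  expect_equal(r$case_carriers, 2)   # homozygote counted once
  expect_equal(r$control_carriers, 1)
  # aggregation consistency: scanning records equals testing the aggregate
  res_records <- carrier_scan(g, "DRB1", m = 5)
  res_counts <- assoc_test(counts, m = 5)
  expect_equal(res_records$p, res_counts$p)
  expect_equal(res_records$or, res_counts$or)
})

test_that("serogroup carriers bound their member-allele carriers", {
  cfg <- control_hap_config(120, 120)
  g <- sample_cohort(cfg, seed = 5)
  sg <- hla_serogroups()
  counts <- carrier_counts(g, "DRB1", units = c("DR8", "DRB1*08:02",
                                                "DRB1*08:03"))
  dr8 <- counts$case_carriers[counts$unit == "DR8"]
  members <- counts$case_carriers[counts$unit != "DR8"]
  expect_gte(dr8, max(members))
  expect_lte(dr8, sum(members))
})

test_that("Bonferroni multiplier defaults to distinct alleles at the locus", {
  g <- make_cohort(
    status = rep(c("case", "control"), each = 4),
    drb1 = rep(list(c("04:05", "08:03"), c("13:02", "15:01"),
                    c("04:05", "04:05"), c("09:01", "12:01")), 2))
  res <- carrier_scan(g, "DRB1")
  expect_equal(res$pc, pmin(1, res$p * 6))  # 6 distinct alleles observed
})

test_that("genotype classes match allele pairs, het carriage and DR groups", {
  g <- make_cohort(
    status = c("case", "case", "case", "case", "control", "control"),
    drb1 = list(c("04:05", "08:02"),   # DR4/DR8
                c("04:05", "04:05"),   # DR4/DR4, 04:05 homozygote
                c("04:05", "13:02"),   # DR4/DR6, one 04:05 copy
                c("04:01", "04:06"),   # DR4/DR4
                c("08:02", "08:03"),   # DR8/DR8
                c("04:05", "09:01")))  # one 04:05 copy, DR4/none
  res <- genotype_scan(g, c("DR4/DR8", "DR4/DR4", "DRB1*04:05/not",
                            "DRB1*04:05/DRB1*04:05", "DR8/DR8", "DR4/DR6"))
  counts <- stats::setNames(res$case_carriers, res$unit)
  expect_equal(unname(counts["DR4/DR8"]), 1)
  expect_equal(unname(counts["DR4/DR4"]), 2)
  expect_equal(unname(counts["DRB1*04:05/not"]), 2)  # het carriers only
  expect_equal(unname(counts["DRB1*04:05/DRB1*04:05"]), 1)
  expect_equal(res$control_carriers[res$unit == "DR8/DR8"], 1)
  expect_true(all(is.na(res$pc)))  # genotype tables carry no corrected P
  expect_error(genotype_class("DR4/DRB1*04:05"), "mix")
})

test_that("empty units are handled by the correction, not by failure", {
  g <- make_cohort(status = c("case", "control"),
                   drb1 = list(c("04:05", "04:05"), c("13:02", "13:02")))
  res <- carrier_scan(g, "DRB1", units = "DRB1*01:01", m = 2)
  expect_equal(res$or, 1)
  expect_equal(res$p, 1)
})

test_that("subgroup comparison reproduces the definite-AIH contrast", {
  # 185 carriers of whom 133 definite, 175 non-carriers of whom 94 definite
  status <- rep("case", 360)
  drb1 <- c(rep(list(c("04:05", "15:01")), 185),
            rep(list(c("13:02", "15:01")), 175))
  definite <- c(rep(TRUE, 133), rep(FALSE, 52), rep(TRUE, 94),
                rep(FALSE, 81))
  g <- make_cohort(status = status, drb1 = drb1, definite_aih = definite)
  res <- subgroup_compare(g, "DRB1*04:05", fields = "definite_aih")
  expect_equal(res$type, "categorical")
  expect_equal(res$carrier_n, 185)
  expect_equal(round(res$carrier_stat, 1), 71.9)
  expect_equal(round(res$p, 4), 0.0005)
})

test_that("subgroup comparison uses rank-sum for numeric fields and
          pairwise deletion for missing values", {
  set.seed(42)
  n <- 200
  carrier <- rep(c(TRUE, FALSE), each = n)
  igg <- stats::rnorm(2 * n, mean = 2120 + 400 * carrier, sd = 300)
  igg[1:5] <- NA  # missing values dropped pairwise
  g <- make_cohort(
    status = rep("case", 2 * n),
    drb1 = lapply(carrier, function(cr) {
      if (cr) c("04:05", "15:01") else c("13:02", "15:01")
    }),
    IgG = igg)
  res <- subgroup_compare(g, "DRB1*04:05", fields = "IgG")
  expect_equal(res$type, "numeric")
  expect_equal(res$carrier_n, n - 5)
  expect_lt(res$p, 0.01)
  # constant phenotype in both arms is uninformative
  g$flat <- TRUE
  expect_equal(subgroup_compare(g, "DRB1*04:05", fields = "flat")$p, 1)
  g$gone <- NA
  expect_error(subgroup_compare(g, "DRB1*04:05", fields = "gone"),
               "missing")
})
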