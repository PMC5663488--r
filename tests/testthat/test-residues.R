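synthetic_residue_table <- function() {
  # three alleles, two positions; V at 11 unique to 04:05
  tibble::tribble(
    ~allele,       ~position, ~residue,
    "DRB1*04:05",  11L,       "V",
    "DRB1*04:05",  13L,       "H",
    "DRB1*13:02",  11L,       "S",
    "DRB1*13:02",  13L,       "S",
    "DRB1*15:01",  11L,       "P",
    "DRB1*15:01",  13L,       "S")
}

test_that("residue lookup is pure, with explicit gaps and errors", {
  tab <- synthetic_residue_table()
  r <- residues_of("DRB1*04:05", tab, positions = c(11, 13))
  expect_equal(r$residue, c("V", "H"))
  gap <- residues_of("DRB1*04:05", tab, positions = c(11, 12))
  expect_true(is.na(gap$residue[gap$position == 12]))
  expect_error(residues_of("DRB1*01:01", tab), "absent")
})

test_that("a residue unique to one allele reproduces that allele's result", {
  cfg <- control_hap_config(150, 150)
  g <- sample_cohort(cfg, seed = 31)
  alleles <- sort(unique(c(g$DRB1_1, g$DRB1_2)))
  # synthetic table: position 11 gives every allele a private residue,
  # position 5 is monomorphic
  tab <- dplyr::bind_rows(
    tibble::tibble(allele = alleles, position = 11L,
                   residue = LETTERS[seq_along(alleles)]),
    tibble::tibble(allele = alleles, position = 5L, residue = "G"))
  res <- residue_carrier_scan(g, tab, locus = "DRB1")
  allele_res <- carrier_scan(g, "DRB1", m = nrow(dplyr::distinct(
    tab[c("position", "residue")])))
  for (i in seq_along(alleles)) {
    ri <- res[res$position == 11 & res$residue == LETTERS[i], ]
    ai <- allele_res[allele_res$unit == alleles[i], ]
    expect_equal(ri$case_carriers, ai$case_carriers)
    expect_equal(ri$control_carriers, ai$control_carriers)
    expect_equal(ri$or, ai$or)
    expect_equal(ri$p, ai$p)
    expect_equal(ri$pc, ai$pc)
  }
  mono <- res[res$position == 5, ]
  expect_equal(nrow(mono), 1)
  expect_equal(mono$or, 1); expect_equal(mono$p, 1)
})

test_that("per-sample residue carriage is bounded by 1..2 values", {
  cfg <- control_hap_config(100, 100)
  g <- sample_cohort(cfg, seed = 32)
  alleles <- sort(unique(c(g$DRB1_1, g$DRB1_2)))
  set.seed(7)
  tab <- tibble::tibble(allele = alleles, position = 20L,
                        residue = sample(c("A", "R", "N"), length(alleles),
                                         replace = TRUE))
  res <- residue_carrier_scan(g, tab, locus = "DRB1", positions = 20)
  n <- 200
  expect_gte(sum(res$case_carriers + res$control_carriers), n)
  expect_lte(sum(res$case_carriers + res$control_carriers), 2 * n)
})

test_that("coverage gaps for observed alleles are an error", {
  g <- make_cohort(status = c("case", "control"),
                   drb1 = list(c("04:05", "13:02"), c("04:05", "15:01")))
  tab <- synthetic_residue_table()
  expect_error(residue_carrier_scan(g, tab, positions = c(11, 12)),
               "cover")
  tab2 <- tab[tab$allele != "DRB1*15:01", ]
  expect_error(residue_carrier_scan(g, tab2), "DRB1\\*15:01")
})

test_that("count-fixture residue scans use the bundled curated table", {
  counts <- read_counts(hla_example("drb1_carrier_counts.tsv"))
  counts <- counts[counts$kind == "allele", ]
  res <- residue_carrier_scan(counts, hla_residues("DRB1"))
  # 57S and 96Y travel only with DRB1*04:05 in the curated table, so their
  # statistics equal the allele's
  a0405 <- assoc_test(counts[counts$unit == "DRB1*04:05", ])
  for (u in c("57S", "96Y")) {
    expect_equal(res$or[res$unit == u], a0405$or)
    expect_equal(res$p[res$unit == u], a0405$p)
  }
  expect_equal(res$direction[res$unit == "57S"], "predisposing")
})
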