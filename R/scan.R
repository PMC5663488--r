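#' Carrier counts from a per-sample cohort
#'
#' Aggregates a genotype tibble into the count-table layout consumed by
#' [assoc_test()], under the dominant model (homozygotes counted once).
#' Units may be alleles at `locus`, or serogroup labels resolved through
#' `serogroups`.
#'
#' @param genotypes A genotype tibble (see [read_genotypes()]).
#' @param locus `"DRB1"` or `"DQB1"`.
#' @param units Character vector of units to count. Default: all distinct
#'   alleles observed at `locus` in the combined cohort, in sorted order.
#' @param serogroups Serogroup map used when a unit is a group label.
#' @return A count tibble with a `kind` column (`allele` or `serogroup`).
#' @export
carrier_counts <- function(genotypes, locus = "DRB1", units = NULL,
                           serogroups = hla_serogroups()) {
  al <- locus_alleles(genotypes, locus)
  if (is.null(units)) units <- sort(unique(c(al$a1, al$a2)))
  is_group <- units %in% serogroups$group
  canon <- units
  if (any(!is_group)) {
    canon[!is_group] <- hla_allele(units[!is_group], locus = locus,
                                   quiet = TRUE)
    off <- !is_group
    off[!is_group] <- allele_locus(canon[!is_group]) != locus
    if (any(off)) {
      stop("unit(s) not at locus ", locus, ": ",
           paste(units[off], collapse = ", "), call. = FALSE)
    }
  }
  case <- genotypes$status == "case"
  rows <- purrr::map2(canon, is_group, function(u, grp) {
    carrier <- if (grp) {
      g1 <- serogroups$group[match(al$a1, serogroups$allele)]
      g2 <- serogroups$group[match(al$a2, serogroups$allele)]
      (!is.na(g1) & g1 == u) | (!is.na(g2) & g2 == u)
    } else {
      al$a1 == u | al$a2 == u
    }
    tibble::tibble(unit = u,
                   case_carriers = sum(carrier & case),
                   case_total = sum(case),
                   control_carriers = sum(carrier & !case),
                   control_total = sum(!case),
                   kind = if (grp) "serogroup" else "allele")
  })
  dplyr::bind_rows(rows)
}

locus_alleles <- function(genotypes, locus) {
  cols <- paste0(locus, c("_1", "_2"))
  if (!all(cols %in% names(genotypes))) {
    stop("cohort lacks ", locus, " columns (", paste(cols, collapse = ", "),
         ")", call. = FALSE)
  }
  a1 <- genotypes[[cols[1]]]; a2 <- genotypes[[cols[2]]]
  if (anyNA(a1) || anyNA(a2)) {
    stop("every record must be genotyped at ", locus, "; missing for: ",
         paste(utils::head(genotypes$sample_id[is.na(a1) | is.na(a2)], 5),
               collapse = ", "), call. = FALSE)
  }
  list(a1 = hla_allele(a1, locus = locus, quiet = TRUE),
       a2 = hla_allele(a2, locus = locus, quiet = TRUE))
}

#' Allele and serogroup carrier-frequency association scan
#'
#' The dominant-model scan: for every unit, carriers are compared between
#' cases and controls with the full statistics stack of [assoc_test()]. The
#' Bonferroni multiplier defaults to the number of distinct alleles observed
#' at the locus in the combined cohort (the allele-level correction rule);
#' serogroup units are reported without a corrected P.
#'
#' @inheritParams carrier_counts
#' @param m Bonferroni multiplier override.
#' @param level Confidence level for the Woolf interval.
#' @return An `hla_assoc` tibble, one row per unit.
#' @export
carrier_scan <- function(genotypes, locus = "DRB1", units = NULL,
                         serogroups = hla_serogroups(), m = NULL,
                         level = 0.95) {
  counts <- carrier_counts(genotypes, locus, units, serogroups)
  if (is.null(m)) {
    al <- locus_alleles(genotypes, locus)
    m <- length(unique(c(al$a1, al$a2)))
  }
  res <- assoc_test(counts, m = m, level = level)
  res$pc[res$kind == "serogroup"] <- NA_real_
  res
}

# ---- genotype classes -------------------------------------------------------

#' Parse a genotype-class label
#'
#' A genotype class is an unordered pair of unit labels separated by `/`:
#' two alleles (`"DRB1*04:05/DRB1*08:02"`), an allele paired with `not`
#' meaning heterozygous carriage of exactly one copy (`"DRB1*04:05/not"`),
#' or two serogroup labels (`"DR4/DR8"`). A sample matches an allele pair iff
#' its two alleles are exactly that multiset; a serogroup pair iff one allele
#' falls in each group (both, for a homozygous group class).
#'
#' @param x Class label.
#' @param locus Locus of allele members.
#' @param serogroups Serogroup map for group labels.
#' @return An object of class `genotype_class`.
#' @export
genotype_class <- function(x, locus = "DRB1", serogroups = hla_serogroups()) {
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("genotype class must be \"X/Y\" or \"X/not\": ", x, call. = FALSE)
  }
  parts <- trimws(parts)
  if (identical(tolower(parts[2]), "not") || identical(tolower(parts[1]), "not")) {
    unit <- parts[tolower(parts) != "not"][1]
    if (unit %in% serogroups$group) {
      stop("heterozygous-carrier classes are defined for alleles, not groups: ",
           x, call. = FALSE)
    }
    out <- list(type = "het_carrier",
                units = hla_allele(unit, locus = locus, quiet = TRUE))
  } else if (all(parts %in% serogroups$group)) {
    out <- list(type = "group_pair", units = sort(parts))
  } else if (any(parts %in% serogroups$group)) {
    stop("cannot mix an allele with a serogroup in one class: ", x,
         call. = FALSE)
  } else {
    out <- list(type = "allele_pair",
                units = sort(hla_allele(parts, locus = locus, quiet = TRUE)))
  }
  out$label <- if (out$type == "het_carrier") paste0(out$units, "/not")
  else paste(out$units, collapse = "/")
  out$locus <- locus
  structure(out, class = "genotype_class")
}

# logical: which samples match a genotype class
match_genotype_class <- function(class, a1, a2, serogroups) {
  switch(class$type,
    het_carrier = (a1 == class$units) + (a2 == class$units) == 1L,
    allele_pair = {
      u <- class$units
      (a1 == u[1] & a2 == u[2]) | (a1 == u[2] & a2 == u[1])
    },
    group_pair = {
      g1 <- serogroups$group[match(a1, serogroups$allele)]
      g2 <- serogroups$group[match(a2, serogroups$allele)]
      u <- class$units
      if (u[1] == u[2]) {
        !is.na(g1) & !is.na(g2) & g1 == u[1] & g2 == u[1]
      } else {
        (!is.na(g1) & !is.na(g2)) &
          ((g1 == u[1] & g2 == u[2]) | (g1 == u[2] & g2 == u[1]))
      }
    })
}

#' Genotype-class association scan
#'
#' Tests each genotype class (see [genotype_class()]) as class members versus
#' all other samples in each arm. No Bonferroni correction is applied, the
#' convention of genotype-frequency tables.
#'
#' @inheritParams carrier_scan
#' @param classes Character vector of class labels, or a list of
#'   `genotype_class` objects.
#' @return An `hla_assoc` tibble, one row per class.
#' @export
genotype_scan <- function(genotypes, classes, locus = "DRB1",
                          serogroups = hla_serogroups(), level = 0.95) {
  al <- locus_alleles(genotypes, locus)
  case <- genotypes$status == "case"
  classes <- lapply(classes, function(cl) {
    if (inherits(cl, "genotype_class")) cl
    else genotype_class(cl, locus = locus, serogroups = serogroups)
  })
  counts <- dplyr::bind_rows(lapply(classes, function(cl) {
    member <- match_genotype_class(cl, al$a1, al$a2, serogroups)
    tibble::tibble(unit = cl$label,
                   case_carriers = sum(member & case),
                   case_total = sum(case),
                   control_carriers = sum(member & !case),
                   control_total = sum(!case),
                   kind = "genotype")
  }))
  assoc_test(counts, m = NULL, level = level)
}

# ---- phenotype subgroups ----------------------------------------------------

#' Compare phenotypes between carriers and non-carriers among cases
#'
#' Stratifies the case arm by carriage of one allele and compares each
#' phenotype field between carriers and non-carriers: logical (or 0/1)
#' fields by the two-sided Fisher exact test on the non-missing 2x2, numeric
#' fields by the two-sided Mann-Whitney test. Missingness is handled by
#' pairwise deletion: every denominator is the count of non-missing values
#' in that arm.
#'
#' @param genotypes A genotype tibble including phenotype columns.
#' @param allele The stratifying allele (canonical form).
#' @param fields Phenotype columns to compare; default: every column that is
#'   not an identifier, status or allele column.
#' @param locus Locus of the stratifying allele.
#' @return A tibble with one row per field: `field`, `type`, per-arm n,
#'   mean/sd (numeric) or count/percent (categorical), and `p`.
#' @export
subgroup_compare <- function(genotypes, allele, fields = NULL,
                             locus = "DRB1") {
  allele <- hla_allele(allele, locus = locus, quiet = TRUE)
  al <- locus_alleles(genotypes, locus)
  cases <- genotypes$status == "case"
  carrier <- (al$a1 == allele | al$a2 == allele)[cases]
  dat <- genotypes[cases, , drop = FALSE]
  if (is.null(fields)) {
    fields <- setdiff(names(dat),
                      c("sample_id", "status",
                        grep("^(DRB1|DQB1|DQA1)_[12]$", names(dat),
                             value = TRUE)))
  }
  miss <- setdiff(fields, names(dat))
  if (length(miss)) {
    stop("phenotype field(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(fields, function(f) {
    v <- dat[[f]]
    if (all(is.na(v))) stop("field ", f, " is entirely missing", call. = FALSE)
    ok <- !is.na(v)
    categorical <- is.logical(v) ||
      (is.numeric(v) && all(v[ok] %in% c(0, 1)))
    if (categorical) {
      vb <- as.logical(v)
      a <- sum(vb & carrier & ok); b <- sum(!vb & carrier & ok)
      c <- sum(vb & !carrier & ok); d <- sum(!vb & !carrier & ok)
      p <- if ((a + c) == 0 || (b + d) == 0) 1 else fisher_exact_p(a, b, c, d)
      tibble::tibble(field = f, type = "categorical",
                     carrier_n = a + b, carrier_stat = 100 * a / (a + b),
                     noncarrier_n = c + d, noncarrier_stat = 100 * c / (c + d),
                     carrier_sd = NA_real_, noncarrier_sd = NA_real_, p = p)
    } else {
      x <- v[carrier & ok]; y <- v[!carrier & ok]
      tibble::tibble(field = f, type = "numeric",
                     carrier_n = length(x), carrier_stat = mean(x),
                     noncarrier_n = length(y), noncarrier_stat = mean(y),
                     carrier_sd = stats::sd(x), noncarrier_sd = stats::sd(y),
                     p = rank_sum_p(x, y))
    }
  })
  dplyr::bind_rows(rows)
}
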