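#' Phase DRB1-DQB1 haplotypes by direct counting
#'
#' Assigns each two-locus genotype its pair of DRB1-DQB1 haplotypes. Because
#' DRB1 and DQB1 are in strong linkage disequilibrium, most samples phase
#' trivially: any sample homozygous at either locus has a single possible
#' phasing. Doubly heterozygous samples have two candidate phasings and are
#' resolved in two steps: (i) if a haplotype catalog is supplied and exactly
#' one candidate consists solely of catalogued haplotypes, that candidate is
#' chosen; (ii) otherwise haplotype frequencies are initialised from the
#' unambiguous samples and each ambiguous sample is assigned to the
#' candidate with the larger product of current frequencies, iterating to a
#' fixed point (at most `max_iter` sweeps). Exact ties are flagged ambiguous
#' and excluded from haplotype counts and downstream denominators.
#'
#' @param genotypes A genotype tibble with both loci typed on every row.
#' @param catalog Optional tibble of permitted haplotypes with columns
#'   `drb1`, `dqb1`.
#' @param max_iter Sweep cap for the iterative frequency rule.
#' @return An object of class `hla_phasing`: a list with `assignments`
#'   (tibble: `sample_id`, `status`, `hap1`, `hap2`, `ambiguous`),
#'   `frequencies` (tibble: `haplotype`, `count`, `freq` over phased
#'   samples), `n_ambiguous` and `n_samples`. Haplotype labels render as
#'   `"DRB1*04:05-DQB1*04:01"`.
#' @export
phase_cohort <- function(genotypes, catalog = NULL, max_iter = 100) {
  drb <- locus_alleles(genotypes, "DRB1")
  dqb <- tryCatch(locus_alleles(genotypes, "DQB1"), error = function(e) {
    stop("phasing needs both loci: ", conditionMessage(e), call. = FALSE)
  })
  n <- nrow(genotypes)
  hapA1 <- hap_label(drb$a1, dqb$a1); hapA2 <- hap_label(drb$a2, dqb$a2)
  hapB1 <- hap_label(drb$a1, dqb$a2); hapB2 <- hap_label(drb$a2, dqb$a1)
  double_het <- drb$a1 != drb$a2 & dqb$a1 != dqb$a2

  take_A <- !double_het          # unique phasing
  resolved <- !double_het
  ambiguous <- rep(FALSE, n)

  idx <- which(double_het)
  if (length(idx) && !is.null(catalog)) {
    cat_haps <- hap_label(hla_allele(catalog$drb1, locus = "DRB1", quiet = TRUE),
                          hla_allele(catalog$dqb1, locus = "DQB1", quiet = TRUE))
    okA <- hapA1[idx] %in% cat_haps & hapA2[idx] %in% cat_haps
    okB <- hapB1[idx] %in% cat_haps & hapB2[idx] %in% cat_haps
    pick <- xor(okA, okB)
    take_A[idx[pick]] <- okA[pick]
    resolved[idx[pick]] <- TRUE
    idx <- idx[!pick]
  }
  if (length(idx)) {
    # iterative frequency assignment, seeded from unambiguous samples
    state <- rep(NA, n)  # TRUE = candidate A, NA = unassigned/tied
    state[resolved] <- take_A[resolved]
    for (iter in seq_len(max_iter)) {
      assigned1 <- ifelse(state, hapA1, hapB1)[!is.na(state)]
      assigned2 <- ifelse(state, hapA2, hapB2)[!is.na(state)]
      freq <- table(c(assigned1, assigned2))
      # pseudocount 0.5 for unseen haplotypes: a candidate sharing an
      # observed haplotype beats one made of two unseen haplotypes, while
      # genuinely symmetric configurations still tie
      f <- function(h) {
        v <- as.numeric(freq[h])
        ifelse(is.na(v), 0.5, v)
      }
      sA <- f(hapA1[idx]) * f(hapA2[idx])
      sB <- f(hapB1[idx]) * f(hapB2[idx])
      new_state <- state
      new_state[idx] <- ifelse(sA > sB, TRUE, ifelse(sB > sA, FALSE, NA))
      if (identical(new_state, state) && iter > 1L) break
      state <- new_state
    }
    take_A[idx] <- ifelse(is.na(state[idx]), NA, state[idx])
    ambiguous[idx] <- is.na(state[idx])
    take_A[ambiguous] <- TRUE  # placeholder; rows are flagged
  }

  hap1 <- ifelse(take_A, hapA1, hapB1)
  hap2 <- ifelse(take_A, hapA2, hapB2)
  hap1[ambiguous] <- NA_character_
  hap2[ambiguous] <- NA_character_

  assignments <- tibble::tibble(
    sample_id = as.character(genotypes$sample_id),
    status = genotypes$status,
    hap1 = hap1, hap2 = hap2, ambiguous = ambiguous)
  phased <- assignments[!assignments$ambiguous, , drop = FALSE]
  freq_tab <- sort(table(c(phased$hap1, phased$hap2)), decreasing = TRUE)
  frequencies <- tibble::tibble(
    haplotype = names(freq_tab),
    count = as.integer(freq_tab),
    freq = as.numeric(freq_tab) / max(1, sum(freq_tab)))
  structure(list(assignments = assignments, frequencies = frequencies,
                 n_ambiguous = sum(ambiguous), n_samples = n),
            class = "hla_phasing")
}

hap_label <- function(drb1, dqb1) paste0(drb1, "-", dqb1)

#' Parse a haplotype or diplotype label
#'
#' @param x A haplotype label `"DRB1*04:05-DQB1*04:01"` (bare `"04:05-04:01"`
#'   also accepted) or a diplotype label joining two haplotypes with `/`.
#' @return For `parse_haplotype()`, the canonical haplotype label; for
#'   `parse_diplotype()`, a sorted character vector of two haplotype labels.
#' @export
parse_haplotype <- function(x) {
  parts <- strsplit(trimws(x), "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("haplotype label must be \"<DRB1>-<DQB1>\": ", x, call. = FALSE)
  }
  hap_label(hla_allele(parts[1], locus = "DRB1", quiet = TRUE),
            hla_allele(parts[2], locus = "DQB1", quiet = TRUE))
}

#' @rdname parse_haplotype
#' @export
parse_diplotype <- function(x) {
  parts <- strsplit(trimws(x), "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("diplotype label must be \"<hap>/<hap>\": ", x, call. = FALSE)
  }
  sort(vapply(parts, parse_haplotype, character(1), USE.NAMES = FALSE))
}

#' @export
print.hla_phasing <- function(x, ...) {
  cat(sprintf("<hla_phasing> %d samples, %d ambiguous, %d haplotypes\n",
              x$n_samples, x$n_ambiguous, nrow(x$frequencies)))
  print(utils::head(x$frequencies, 10))
  invisible(x)
}

#' Tidy methods for phasing results
#'
#' `tidy()` returns the cohort haplotype frequency table; `glance()` a
#' one-row summary (samples, ambiguous samples, distinct haplotypes).
#'
#' @param x An `hla_phasing` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.hla_phasing <- function(x, ...) x$frequencies

#' @rdname tidy.hla_phasing
#' @exportS3Method generics::glance
glance.hla_phasing <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_ambiguous = x$n_ambiguous,
                 n_haplotypes = nrow(x$frequencies))
}

phasing_arm <- function(phasing) {
  a <- phasing$assignments
  a[!a$ambiguous, , drop = FALSE]
}

#' Haplotype carrier-frequency association scan
#'
#' For each haplotype, a carrier is a phased sample with at least one copy;
#' carriers are compared between cases and controls with the full statistics
#' stack. Ambiguous samples are excluded from both numerators and
#' denominators. No corrected P is reported by default, the convention of
#' haplotype tables.
#'
#' @param phasing An `hla_phasing` object for a cohort containing both arms.
#' @param units Haplotype labels to test; default all observed haplotypes.
#' @param m Optional Bonferroni multiplier.
#' @param level Confidence level.
#' @return An `hla_assoc` tibble.
#' @export
haplotype_carrier_scan <- function(phasing, units = NULL, m = NULL,
                                   level = 0.95) {
  ph <- phasing_arm(phasing)
  if (is.null(units)) units <- phasing$frequencies$haplotype
  else units <- vapply(units, parse_haplotype, character(1), USE.NAMES = FALSE)
  case <- ph$status == "case"
  counts <- dplyr::bind_rows(lapply(units, function(u) {
    carrier <- ph$hap1 == u | ph$hap2 == u
    tibble::tibble(unit = u,
                   case_carriers = sum(carrier & case),
                   case_total = sum(case),
                   control_carriers = sum(carrier & !case),
                   control_total = sum(!case),
                   kind = "haplotype")
  }))
  res <- assoc_test(counts, m = m, level = level)
  if (is.null(m)) res$pc <- NA_real_
  res
}

#' Diplotype association scan
#'
#' Tests diplotype classes (a specific unordered pair of haplotypes, or
#' `"<hap>/not"` for heterozygous carriage of exactly one copy) as members
#' versus all other phased samples in each arm. Structural zeros are handled
#' by the conditional zero-cell correction of [odds_ratio()].
#'
#' @inheritParams haplotype_carrier_scan
#' @param classes Character vector of diplotype class labels.
#' @return An `hla_assoc` tibble.
#' @export
diplotype_scan <- function(phasing, classes, level = 0.95) {
  ph <- phasing_arm(phasing)
  case <- ph$status == "case"
  counts <- dplyr::bind_rows(lapply(classes, function(cl) {
    parts <- strsplit(trimws(cl), "/", fixed = TRUE)[[1]]
    if (length(parts) == 2L && tolower(parts[2]) == "not") {
      u <- parse_haplotype(parts[1])
      member <- (ph$hap1 == u) + (ph$hap2 == u) == 1L
      label <- paste0(u, "/not")
    } else {
      pair <- parse_diplotype(cl)
      member <- (ph$hap1 == pair[1] & ph$hap2 == pair[2]) |
        (ph$hap1 == pair[2] & ph$hap2 == pair[1])
      label <- paste(pair, collapse = "/")
    }
    tibble::tibble(unit = label,
                   case_carriers = sum(member & case),
                   case_total = sum(case),
                   control_carriers = sum(member & !case),
                   control_total = sum(!case),
                   kind = "diplotype")
  }))
  assoc_test(counts, m = NULL, level = level)
}
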