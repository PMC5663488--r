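#' Exact and asymptotic inference for 2x2 carrier tables
#'
#' The statistical core of the package. A carrier table is the 2x2 table
#' \preformatted{
#'              carrier   non-carrier
#'   cases         a          b
#'   controls      c          d
#' }
#' tested under the dominant model: `a` counts cases with at least one copy
#' of the unit (allele, serogroup, haplotype, residue), homozygotes counted
#' once.
#'
#' `odds_ratio()` returns the cross-product ratio `(a*d)/(b*c)`. When any
#' cell is zero, 0.5 is added to all four cells first (Haldane-Anscombe);
#' tables with all cells positive are left uncorrected. `woolf_ci()` is the
#' log-normal interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`
#' computed on the same (possibly corrected) cells; at the default 95% level
#' the conventional two-decimal quantile z = 1.96 is used (the rounding
#' convention of the published tables this stack reproduces), and
#' `qnorm((1 + level) / 2)` otherwise. `fisher_exact_p()` is the
#' two-sided Fisher exact P under the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table (relative tie
#' tolerance 1e-7).
#'
#' @param a,b,c,d Non-negative integer cell counts, vectorised.
#' @param level Confidence level in (0, 1).
#' @return `odds_ratio()` and `fisher_exact_p()` return numeric vectors;
#'   `woolf_ci()` a tibble with columns `ci_low`, `ci_high`.
#' @examples
#' odds_ratio(185, 175, 243, 783)        # 3.41
#' odds_ratio(1, 359, 0, 1026)           # 8.57 via the zero-cell correction
#' woolf_ci(185, 175, 243, 783)          # 2.65 - 4.38
#' fisher_exact_p(185, 175, 243, 783)    # 1.89e-21
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- check_cells(a, b, c, d)
  with(cells, (a * d) / (b * c))
}

# validate counts and apply the conditional Haldane-Anscombe correction
check_cells <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  cells <- cbind(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(cells) == 0)) {
    stop("empty 2x2 table", call. = FALSE)
  }
  zero <- rowSums(cells == 0) > 0
  cells[zero, ] <- cells[zero, , drop = FALSE] + 0.5
  list(a = unname(cells[, 1]), b = unname(cells[, 2]),
       c = unname(cells[, 3]), d = unname(cells[, 4]), corrected = zero)
}

#' @rdname odds_ratio
#' @export
woolf_ci <- function(a, b, c, d, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single probability in (0, 1)", call. = FALSE)
  }
  cells <- check_cells(a, b, c, d)
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm((1 + level) / 2)
  lor <- with(cells, log((a * d) / (b * c)))
  se <- with(cells, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  tibble::tibble(ci_low = exp(lor - z * se), ci_high = exp(lor + z * se))
}

#' @rdname odds_ratio
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  cells <- cbind(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; c1 <- a[i] + c[i]
    if (r1 + r2 == 0) stop("empty 2x2 table", call. = FALSE)
    k <- max(0, c1 - r2):min(r1, c1)
    pr <- stats::dhyper(k, r1, r2, c1)
    p_obs <- pr[match(a[i], k)]
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Bonferroni correction at the allele or residue level
#'
#' Multiplies an uncorrected P by the number of units tested and caps at 1.
#' Mirroring the reporting convention of HLA association tables, a corrected
#' value is conventionally reported as "NS" when the uncorrected P is already
#' at or above 0.05; [assoc_test()] carries that flag in its `ns` column.
#'
#' @param p Numeric vector of uncorrected P values.
#' @param m Number of units tested (single positive integer).
#' @return Numeric vector of corrected P values.
#' @examples
#' bonferroni_p(0.0298, 30) # 0.8949 (allele-level correction, 30 alleles)
#' @export
bonferroni_p <- function(p, m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("`m` must be a single count >= 1", call. = FALSE)
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, p * m)
}

#' Two-sided Mann-Whitney comparison
#'
#' Rank-sum comparison of a numeric phenotype between two arms, used for the
#' continuous fields of carrier-stratified subgroup tables. Missing values
#' are dropped pairwise; an all-missing sample is an error. The exact
#' distribution is used for small untied samples (via [stats::wilcox.test()]),
#' the midrank normal approximation otherwise.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-arm size for which the exact P is attempted.
#' @return The two-sided P value.
#' @export
rank_sum_p <- function(x, y, exact_max = 50) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("both samples must contain non-missing values", call. = FALSE)
  }
  if (identical(sort(x), sort(y))) return(1)
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value
  )
}

#' Association statistics for a table of carrier counts
#'
#' Turns count rows (one unit per row) into full association results: carrier
#' frequencies in percent, odds ratio with conditional zero-cell correction,
#' Woolf confidence interval, two-sided Fisher exact P, optional Bonferroni
#' corrected P, the conventional NS flag (uncorrected P >= 0.05), and the
#' direction of association.
#'
#' @param counts A tibble with columns `unit`, `case_carriers`, `case_total`,
#'   `control_carriers`, `control_total` (see [read_counts()]).
#' @param m Bonferroni multiplier: number of units tested. `NULL` leaves
#'   `pc` as `NA` (tables that print no corrected value).
#' @param level Confidence level for the Woolf interval.
#' @return A tibble of class `hla_assoc`, one row per unit, with columns
#'   `unit`, the four counts, `case_freq`, `control_freq` (percent), `or`,
#'   `ci_low`, `ci_high`, `p`, `pc`, `ns`, `direction`.
#' @examples
#' counts <- read_counts(hla_example("drb1_carrier_counts.tsv"))
#' assoc_test(dplyr::filter(counts, kind == "allele"), m = 30)
#' @export
assoc_test <- function(counts, m = NULL, level = 0.95) {
  need <- c("unit", "case_carriers", "case_total",
            "control_carriers", "control_total")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    stop("`counts` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  a <- counts$case_carriers
  b <- counts$case_total - a
  c <- counts$control_carriers
  d <- counts$control_total - c
  p <- fisher_exact_p(a, b, c, d)
  ci <- woolf_ci(a, b, c, d, level = level)
  or <- odds_ratio(a, b, c, d)
  out <- tibble::tibble(
    unit = counts$unit,
    case_carriers = a, case_total = counts$case_total,
    control_carriers = c, control_total = counts$control_total,
    case_freq = 100 * a / counts$case_total,
    control_freq = 100 * c / counts$control_total,
    or = or, ci_low = ci$ci_low, ci_high = ci$ci_high,
    p = p,
    pc = if (is.null(m)) NA_real_ else bonferroni_p(p, m),
    ns = p >= 0.05,
    direction = dplyr::case_when(
      p >= 0.05 ~ "none",
      or > 1 ~ "predisposing",
      or < 1 ~ "protective",
      TRUE ~ "none"
    )
  )
  keep <- setdiff(names(counts), c(names(out), "case_carriers",
                                   "control_carriers"))
  for (col in keep) out[[col]] <- counts[[col]]
  new_hla_assoc(out)
}

new_hla_assoc <- function(x) {
  class(x) <- unique(c("hla_assoc", class(tibble::tibble())))
  x
}

#' Format P values the way association tables print them
#'
#' @param p Numeric vector.
#' @param paper_style Use `1.89X10^-21` notation instead of `1.89e-21`.
#' @return Character vector.
#' @export
format_p <- function(p, paper_style = FALSE) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p >= 1e-4, sprintf("%.4f", p),
                       sprintf("%.2e", p)))
  if (paper_style) {
    out <- sub("e-0?(\\d+)$", "X10^-\\1", out)
  }
  out
}
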