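#' Allele-to-residue lookup tables
#'
#' A residue table maps each allele to the one-letter amino acid it encodes
#' at polymorphic positions of the mature protein (position 1 = first
#' residue after the signal peptide). `read_residue_table()` reads a TSV
#' with columns `allele`, `position`, `residue`; `hla_residues()` returns
#' the bundled curated table for the DRbeta (`"DRB1"`) or DQbeta (`"DQB1"`)
#' chain. The bundled tables are an implementer-curated two-field consensus
#' restricted to the scanned positions; analyses of real data should supply
#' a table derived from the current IMGT/HLA protein alignments.
#'
#' @param path Path to a residue TSV.
#' @param locus `"DRB1"` or `"DQB1"` for the bundled table.
#' @return A tibble with columns `allele`, `position`, `residue`.
#' @export
read_residue_table <- function(path) {
  tab <- read_tsv_strict(path, c("allele", "position", "residue"))
  tab$allele <- hla_allele(tab$allele, quiet = TRUE)
  tab$position <- as.integer(tab$position)
  if (anyNA(tab$position) || any(tab$position < 1)) {
    stop(path, ": positions must be mature-protein indices >= 1",
         call. = FALSE)
  }
  if (any(!grepl("^[A-Z]$", tab$residue))) {
    stop(path, ": residues must be one-letter amino acid codes",
         call. = FALSE)
  }
  if (anyDuplicated(tab[c("allele", "position")])) {
    stop(path, ": more than one residue for an (allele, position) pair",
         call. = FALSE)
  }
  tab
}

#' @rdname read_residue_table
#' @export
hla_residues <- function(locus = c("DRB1", "DQB1")) {
  locus <- match.arg(locus)
  read_residue_table(system.file(
    "extdata", paste0("residues_", tolower(locus), ".tsv"),
    package = "hlaassoc", mustWork = TRUE))
}

#' Residues encoded by an allele
#'
#' Pure lookup, no inference: positions not covered for the allele are
#' returned as `NA` gaps.
#'
#' @param allele A single canonical allele.
#' @param table A residue table (see [read_residue_table()]).
#' @param positions Positions to report; default all positions in the table.
#' @return A tibble with columns `position`, `residue` (`NA` = gap).
#' @export
residues_of <- function(allele, table, positions = NULL) {
  allele <- hla_allele(allele, quiet = TRUE)
  if (!allele %in% table$allele) {
    stop("allele absent from residue table: ", allele, call. = FALSE)
  }
  if (is.null(positions)) positions <- sort(unique(table$position))
  sub <- table[table$allele == allele, , drop = FALSE]
  tibble::tibble(position = as.integer(positions),
                 residue = sub$residue[match(positions, sub$position)])
}

#' Amino-acid residue carrier-frequency association scan
#'
#' Translates allele carriage into residue carriage and runs the carrier
#' statistics stack per (position, residue) unit. A sample carries residue
#' `r` at position `p` iff at least one of its alleles encodes `r` at `p`.
#' The Bonferroni multiplier defaults to the number of residue units tested
#' (the residue-level correction rule).
#'
#' Two input forms are accepted. A per-sample genotype tibble gives exact
#' carrier counts. An allele carrier-count tibble (columns as in
#' [read_counts()]) gives residue counts by summing the carrier counts of
#' the alleles encoding the residue, capped at the arm total; this is exact
#' when the residue is carried through a single allele and an upper bound
#' otherwise, and is the form used with published count tables.
#'
#' @param x Genotype tibble or allele count tibble.
#' @param table Residue table covering every observed allele at the scanned
#'   positions (a coverage gap is an error).
#' @param locus Locus scanned.
#' @param positions Positions to scan; default all polymorphic positions in
#'   `table`.
#' @param m Bonferroni multiplier override.
#' @param level Confidence level.
#' @return An `hla_assoc` tibble with extra columns `position`, `residue`.
#' @export
residue_carrier_scan <- function(x, table, locus = "DRB1", positions = NULL,
                                 m = NULL, level = 0.95) {
  if (is.null(positions)) positions <- sort(unique(table$position))
  from_counts <- all(c("case_carriers", "case_total") %in% names(x))
  if (from_counts) {
    alleles <- hla_allele(x$unit, locus = locus, quiet = TRUE)
  } else {
    al <- locus_alleles(x, locus)
    alleles <- unique(c(al$a1, al$a2))
  }
  cov <- table[table$position %in% positions, , drop = FALSE]
  gaps <- vapply(alleles, function(a) {
    length(setdiff(positions, cov$position[cov$allele == a])) > 0
  }, logical(1))
  if (any(gaps)) {
    stop("residue table does not cover allele(s) at all scanned positions: ",
         paste(alleles[gaps], collapse = ", "), call. = FALSE)
  }

  units <- dplyr::distinct(cov[cov$allele %in% alleles,
                               c("position", "residue")])
  units <- dplyr::arrange(units, .data$position, .data$residue)
  lookup <- function(a, p) cov$residue[cov$allele == a & cov$position == p]

  counts <- purrr::pmap(units, function(position, residue) {
    enc <- unique(cov$allele[cov$position == position &
                               cov$residue == residue])
    if (from_counts) {
      sel <- alleles %in% enc
      tibble::tibble(
        unit = paste0(position, residue),
        case_carriers = min(sum(x$case_carriers[sel]), x$case_total[1]),
        case_total = x$case_total[1],
        control_carriers = min(sum(x$control_carriers[sel]),
                               x$control_total[1]),
        control_total = x$control_total[1],
        kind = "residue", position = position, residue = residue)
    } else {
      carrier <- al$a1 %in% enc | al$a2 %in% enc
      case <- x$status == "case"
      tibble::tibble(
        unit = paste0(position, residue),
        case_carriers = sum(carrier & case), case_total = sum(case),
        control_carriers = sum(carrier & !case),
        control_total = sum(!case),
        kind = "residue", position = position, residue = residue)
    }
  })
  counts <- dplyr::bind_rows(counts)
  if (is.null(m)) m <- nrow(units)
  assoc_test(counts, m = m, level = level)
}
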