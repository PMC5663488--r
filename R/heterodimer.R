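#' DRB1-DQB1 to DQA1 linkage map
#'
#' On a conserved haplotype, the DQA1 allele travelling with a given
#' DRB1-DQB1 pair can be presumed from population haplotype structure.
#' `read_dqa1_map()` reads a TSV with columns `drb1`, `dqb1`, `dqa1`;
#' `hla_dqa1_map()` returns the bundled default, which contains exactly the
#' three presumed assignments used for the high-risk Japanese AIH
#' diplotypes (04:05-04:01 -> DQA1*03:03, 08:02-03:02 -> DQA1*03:01,
#' 08:03-06:01 -> DQA1*01:03) and nothing inferred beyond them.
#'
#' @param path Path to a linkage-map TSV.
#' @return A tibble with columns `haplotype`, `dqa1`.
#' @export
read_dqa1_map <- function(path) {
  tab <- read_tsv_strict(path, c("drb1", "dqb1", "dqa1"))
  hap <- hap_label(hla_allele(tab$drb1, locus = "DRB1", quiet = TRUE),
                   hla_allele(tab$dqb1, locus = "DQB1", quiet = TRUE))
  if (anyDuplicated(hap)) {
    stop(path, ": more than one DQA1 for a haplotype", call. = FALSE)
  }
  tibble::tibble(haplotype = hap,
                 dqa1 = hla_allele(tab$dqa1, locus = "DQA1", quiet = TRUE))
}

#' @rdname read_dqa1_map
#' @export
hla_dqa1_map <- function() {
  read_dqa1_map(system.file("extdata", "dqa1_map.tsv",
                            package = "hlaassoc", mustWork = TRUE))
}

#' Enumerate cis and trans DQ alpha-beta heterodimers of a diplotype
#'
#' A DRB1-DQB1 diplotype implies four DQ alpha-beta molecules once each
#' haplotype's DQA1 allele is known: the two cis pairs combine the DQA1 and
#' DQB1 products of the same chromosome, the two trans pairs combine DQA1 of
#' one chromosome with DQB1 of the other. Optional free-text stability
#' labels are attached from a user-supplied lookup (columns `dqa1`, `dqb1`,
#' `label`); pairs outside the lookup are labelled `"unknown"`. Stability is
#' never computed by the package.
#'
#' @param diplotype A diplotype label
#'   (`"DRB1*04:05-DQB1*04:01/DRB1*08:02-DQB1*03:02"`) or a character vector
#'   of two haplotype labels.
#' @param map A DQA1 linkage map (see [hla_dqa1_map()]); both haplotypes
#'   must be covered.
#' @param stability Optional stability lookup tibble.
#' @return A tibble with four rows and columns `dqa1`, `dqb1`, `phase`
#'   (`cis`/`trans`) and `stability`.
#' @examples
#' enumerate_heterodimers("DRB1*04:05-DQB1*04:01/DRB1*08:02-DQB1*03:02")
#' @export
enumerate_heterodimers <- function(diplotype, map = hla_dqa1_map(),
                                   stability = NULL) {
  haps <- if (length(diplotype) == 1L) parse_diplotype(diplotype)
  else sort(vapply(diplotype, parse_haplotype, character(1),
                   USE.NAMES = FALSE))
  if (length(haps) != 2L) {
    stop("a diplotype is a pair of haplotypes", call. = FALSE)
  }
  miss <- setdiff(haps, map$haplotype)
  if (length(miss)) {
    stop("haplotype(s) not covered by the DQA1 linkage map: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  alpha <- map$dqa1[match(haps, map$haplotype)]
  beta <- sub("^.*-", "", haps)
  out <- tibble::tibble(
    dqa1 = c(alpha[1], alpha[2], alpha[1], alpha[2]),
    dqb1 = c(beta[1], beta[2], beta[2], beta[1]),
    phase = c("cis", "cis", "trans", "trans"))
  out$stability <- "unknown"
  if (!is.null(stability)) {
    key <- paste(hla_allele(stability$dqa1, locus = "DQA1", quiet = TRUE),
                 hla_allele(stability$dqb1, locus = "DQB1", quiet = TRUE))
    hit <- match(paste(out$dqa1, out$dqb1), key)
    out$stability[!is.na(hit)] <- stability$label[hit[!is.na(hit)]]
  }
  out
}
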