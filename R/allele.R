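#' Parse and normalise HLA allele names
#'
#' Normalises HLA class II allele strings to canonical two-field form
#' `"<locus>*<dd>:<dd>"`, e.g. `"DRB1*04:05"`. Accepted inputs are fully
#' qualified names (`"DRB1*04:05"`), higher-resolution names whose extra
#' fields are dropped (`"DRB1*04:05:01"` becomes `"DRB1*04:05"`, with a
#' message), and bare field strings (`"04:05"`) combined with a `locus` hint.
#'
#' @param x Character vector of allele strings.
#' @param locus Optional locus hint (`"DRB1"`, `"DQB1"` or `"DQA1"`), recycled
#'   along `x`. Required for bare names; if supplied together with a
#'   locus-qualified name the two must agree.
#' @param quiet Suppress the truncation message.
#' @return A character vector of canonical allele names.
#' @examples
#' hla_allele(c("DRB1*04:05", "DRB1*04:05:01"))
#' hla_allele("04:01", locus = "DQB1")
#' @export
hla_allele <- function(x, locus = NULL, quiet = FALSE) {
  if (length(x) == 0L) return(character())
  x_chr <- trimws(as.character(x))
  if (anyNA(x_chr) || any(x_chr == "")) {
    stop("allele strings must be non-empty", call. = FALSE)
  }
  loci <- c("DRB1", "DQB1", "DQA1")
  if (!is.null(locus)) {
    locus <- rep_len(as.character(locus), length(x_chr))
    bad_hint <- !is.na(locus) & !locus %in% loci
    if (any(bad_hint)) {
      stop("unknown locus hint: ", paste(unique(locus[bad_hint]), collapse = ", "),
           call. = FALSE)
    }
  }

  has_star <- grepl("*", x_chr, fixed = TRUE)
  pre <- ifelse(has_star, sub("\\*.*$", "", x_chr), NA_character_)
  fields_str <- ifelse(has_star, sub("^[^*]*\\*", "", x_chr), x_chr)

  bad_locus <- has_star & !pre %in% loci
  if (any(bad_locus)) {
    stop("unsupported locus in allele name: ",
         paste(unique(x_chr[bad_locus]), collapse = ", "), call. = FALSE)
  }
  out_locus <- pre
  if (!is.null(locus)) {
    conflict <- has_star & !is.na(locus) & pre != locus
    if (any(conflict)) {
      stop("locus hint conflicts with allele name: ",
           paste(unique(x_chr[conflict]), collapse = ", "), call. = FALSE)
    }
    out_locus <- ifelse(has_star, pre, locus)
  }
  if (anyNA(out_locus)) {
    stop("no locus for bare allele name(s): ",
         paste(unique(x_chr[is.na(out_locus)]), collapse = ", "),
         "; supply `locus`", call. = FALSE)
  }

  # two-digit fields separated by ':'; fields beyond the second are dropped
  ok <- grepl("^\\d{2}:\\d{2}(:\\d{1,4}[A-Z]?)*$", fields_str)
  if (any(!ok)) {
    stop("malformed allele name: ",
         paste(unique(x_chr[!ok]), collapse = ", "),
         " (expected two-digit fields like \"04:05\")", call. = FALSE)
  }
  truncated <- grepl("^\\d{2}:\\d{2}:", fields_str)
  if (any(truncated) && !quiet) {
    message("truncated ", sum(truncated),
            " allele name(s) to two-field resolution (e.g. ",
            x_chr[truncated][1L], ")")
  }
  two_field <- sub("^(\\d{2}:\\d{2}).*$", "\\1", fields_str)
  paste0(out_locus, "*", two_field)
}

#' Locus and name fields of a canonical allele
#'
#' @param allele Character vector of canonical allele names (see
#'   [hla_allele()]).
#' @return `allele_locus()` returns the locus part; `allele_name()` the
#'   two-field name part.
#' @export
allele_locus <- function(allele) {
  sub("\\*.*$", "", hla_allele(allele, quiet = TRUE))
}

#' @rdname allele_locus
#' @export
allele_name <- function(allele) {
  sub("^.*\\*", "", hla_allele(allele, quiet = TRUE))
}

#' Serological groups of DRB1 alleles
#'
#' `read_serogroups()` reads a tab-separated file with columns `group` and
#' `allele` (canonical form). `hla_serogroups()` returns the bundled default:
#' the DR4, DR6 and DR8 groups as used in Japanese type 1 autoimmune
#' hepatitis case-control work (DR4: seven DRB1*04 alleles; DR6: nine
#' DRB1*13/*14 alleles; DR8: three DRB1*08 alleles). Groups at a locus must
#' be disjoint.
#'
#' @param path Path to a serogroup TSV.
#' @return A tibble with columns `group` and `allele`.
#' @export
read_serogroups <- function(path) {
  tab <- read_tsv_strict(path, c("group", "allele"))
  tab$allele <- hla_allele(tab$allele, quiet = TRUE)
  dup <- duplicated(tab$allele)
  if (any(dup)) {
    stop("allele(s) assigned to more than one serogroup: ",
         paste(unique(tab$allele[dup]), collapse = ", "), call. = FALSE)
  }
  tab
}

#' @rdname read_serogroups
#' @export
hla_serogroups <- function() {
  read_serogroups(system.file("extdata", "serogroups.tsv",
                              package = "hlaassoc", mustWork = TRUE))
}

#' Serological group membership
#'
#' Returns the unique serogroup containing each allele, or `NA` for alleles
#' outside every group. Errors when an allele's locus does not appear in the
#' map at all (so a DQB1 allele cannot silently fall through a DRB1-only map).
#'
#' @param allele Character vector of canonical alleles.
#' @param groups Serogroup map as returned by [hla_serogroups()].
#' @return Character vector of group labels (`NA` when ungrouped).
#' @examples
#' serogroup_of(c("DRB1*04:10", "DRB1*08:03", "DRB1*09:01"))
#' @export
serogroup_of <- function(allele, groups = hla_serogroups()) {
  allele <- hla_allele(allele, quiet = TRUE)
  map_loci <- unique(allele_locus(groups$allele))
  off <- !allele_locus(allele) %in% map_loci
  if (any(off)) {
    stop("locus not covered by the serogroup map: ",
         paste(unique(allele_locus(allele)[off]), collapse = ", "),
         call. = FALSE)
  }
  groups$group[match(allele, groups$allele)]
}

#' Shared-epitope classification of DRB1 alleles
#'
#' The shared epitope is the conserved QKRAA/RRRAA/QRRAA motif at DRbeta
#' positions 70-74 carried by rheumatoid-arthritis risk alleles.
#' `read_shared_epitope()` reads a TSV with columns `allele` and
#' `motif_70_74`; `hla_shared_epitope()` returns the bundled default set
#' (DRB1*01:01, *04:01, *04:04, *04:05, *04:10, *10:01, *14:02, *14:06).
#'
#' @param path Path to a shared-epitope TSV.
#' @return A tibble with columns `allele` and `motif_70_74`.
#' @export
read_shared_epitope <- function(path) {
  tab <- read_tsv_strict(path, c("allele", "motif_70_74"))
  tab$allele <- hla_allele(tab$allele, quiet = TRUE)
  bad <- !tab$motif_70_74 %in% c("QKRAA", "RRRAA", "QRRAA")
  if (any(bad)) {
    stop("motif outside the shared-epitope set: ",
         paste(unique(tab$motif_70_74[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(allele_locus(tab$allele) != "DRB1")) {
    stop("shared-epitope alleles must be at DRB1", call. = FALSE)
  }
  tab
}

#' @rdname read_shared_epitope
#' @export
hla_shared_epitope <- function() {
  read_shared_epitope(system.file("extdata", "shared_epitope.tsv",
                                  package = "hlaassoc", mustWork = TRUE))
}

#' @rdname read_shared_epitope
#' @param allele Character vector of canonical DRB1 alleles.
#' @param se Shared-epitope table as returned by [hla_shared_epitope()].
#' @return `is_shared_epitope()` returns a logical vector.
#' @examples
#' is_shared_epitope(c("DRB1*04:05", "DRB1*13:02"))
#' @export
is_shared_epitope <- function(allele, se = hla_shared_epitope()) {
  allele <- hla_allele(allele, quiet = TRUE)
  if (any(allele_locus(allele) != "DRB1")) {
    stop("shared-epitope status is defined for DRB1 alleles only",
         call. = FALSE)
  }
  allele %in% se$allele
}
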