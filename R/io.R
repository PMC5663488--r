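#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# strict TSV reader: required header, '#' comment lines allowed. Columns are
# read as character and re-typed with type.convert so allele names like
# "04:05" are never mistaken for times.
read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(tab)) {
    tab[[col]] <- utils::type.convert(tab[[col]], as.is = TRUE)
  }
  tibble::as_tibble(tab)
}

#' Read a per-sample genotype table
#'
#' Expects a tab-separated file with header columns `sample_id`, `status`,
#' `DRB1_1`, `DRB1_2` and optionally `DQB1_1`, `DQB1_2`, followed by free
#' phenotype columns (e.g. `sex`, `age_at_onset`, `ANA`, `ASMA`, `IgG`,
#' `IAIHG_score`, `definite_aih`). Status tokens are `case`/`control`.
#' Alleles are normalised with [hla_allele()]; the first failing row is
#' reported by number. Duplicate sample ids are an error. A one-line summary
#' (cases, controls, DQB1 availability) is emitted as a message.
#'
#' @param path Path to the genotype TSV.
#' @param quiet Suppress the summary message.
#' @return A tibble with canonical allele columns and any phenotype columns.
#' @export
read_genotypes <- function(path, quiet = FALSE) {
  tab <- read_tsv_strict(path, c("sample_id", "status", "DRB1_1", "DRB1_2"))
  tab$sample_id <- as.character(tab$sample_id)
  dup <- duplicated(tab$sample_id)
  if (any(dup)) {
    stop(path, ": duplicated sample_id: ",
         paste(unique(tab$sample_id[dup]), collapse = ", "), call. = FALSE)
  }
  bad_status <- !tab$status %in% c("case", "control")
  if (any(bad_status)) {
    stop(path, ": unknown status token in row(s) ",
         paste(which(bad_status), collapse = ", "),
         " (expected \"case\" or \"control\")", call. = FALSE)
  }
  has_dqb1 <- all(c("DQB1_1", "DQB1_2") %in% names(tab))
  allele_cols <- c("DRB1_1", "DRB1_2", if (has_dqb1) c("DQB1_1", "DQB1_2"))
  for (col in allele_cols) {
    locus <- sub("_[12]$", "", col)
    vals <- tab[[col]]
    idx <- which(!is.na(vals))
    if (!length(idx)) next
    parsed <- tryCatch(
      hla_allele(vals[idx], locus = locus, quiet = quiet),
      error = function(e) {
        ok <- vapply(vals[idx], function(v) {
          !inherits(tryCatch(hla_allele(v, locus = locus, quiet = TRUE),
                             error = identity), "error")
        }, logical(1))
        stop(path, ": allele parse failure in column ", col, ", row(s) ",
             paste(idx[!ok], collapse = ", "), ": ", conditionMessage(e),
             call. = FALSE)
      })
    tab[[col]] <- replace(vals, idx, parsed)
  }
  na_drb1 <- is.na(tab$DRB1_1) | is.na(tab$DRB1_2)
  if (any(na_drb1)) {
    stop(path, ": missing DRB1 allele in row(s) ",
         paste(which(na_drb1), collapse = ", "), call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("read %d samples (%d cases, %d controls)%s",
                    nrow(tab), sum(tab$status == "case"),
                    sum(tab$status == "control"),
                    if (has_dqb1) {
                      sprintf("; DQB1 typed for %d",
                              sum(!is.na(tab$DQB1_1) & !is.na(tab$DQB1_2)))
                    } else "; no DQB1 columns"))
  }
  tab
}

#' Read a pre-aggregated carrier/genotype/haplotype count table
#'
#' Reads a TSV with columns `unit`, `case_carriers`, `case_total`,
#' `control_carriers`, `control_total`; extra columns (e.g. a `kind` tag or
#' published statistics used for regression checks) are kept as-is. Rows are
#' validated: counts non-negative integers, carriers never exceeding totals.
#'
#' @param path Path to the count TSV.
#' @return A validated tibble of count rows.
#' @export
read_counts <- function(path) {
  tab <- read_tsv_strict(path, c("unit", "case_carriers", "case_total",
                                 "control_carriers", "control_total"))
  num <- c("case_carriers", "case_total", "control_carriers", "control_total")
  for (col in num) {
    v <- tab[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v))) {
      stop(path, ": column ", col, " must hold non-negative integer counts",
           call. = FALSE)
    }
    tab[[col]] <- as.integer(v)
  }
  over <- tab$case_carriers > tab$case_total |
    tab$control_carriers > tab$control_total
  if (any(over)) {
    stop(path, ": carriers exceed totals in row(s) ",
         paste(which(over), collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write a result table as TSV with a provenance header
#'
#' Prepends a single `#` comment line recording the package version, the
#' writing function, optional input descriptions and the seed, so every
#' output file documents how it was produced.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param inputs Optional character vector describing the inputs.
#' @param seed Optional integer seed to record.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, inputs = NULL, seed = NULL) {
  header <- sprintf("# hlaassoc %s | %s%s%s",
                    as.character(utils::packageVersion("hlaassoc")),
                    format(Sys.time(), "%Y-%m-%d"),
                    if (length(inputs)) paste0(" | inputs: ",
                                               paste(inputs, collapse = ", ")) else "",
                    if (!is.null(seed)) paste0(" | seed: ", seed) else "")
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Paths to bundled data files
#'
#' Convenience accessor for the package's bundled maps and count fixtures
#' under `extdata/`. Called without arguments it lists the available files.
#'
#' @param file File name, e.g. `"drb1_carrier_counts.tsv"`.
#' @return A file path, or a vector of available file names.
#' @export
hla_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "hlaassoc", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled file called ", file, call. = FALSE)
  path
}
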