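#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for association scans
#'
#' An `hla_assoc` object is already a tibble; `tidy()` returns it with the
#' bookkeeping columns dropped, `glance()` a one-row summary (units tested,
#' significant before and after correction).
#'
#' @param x An `hla_assoc` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.hla_assoc <- function(x, ...) {
  tibble::as_tibble(x)[intersect(
    c("unit", "case_freq", "control_freq", "or", "ci_low", "ci_high",
      "p", "pc", "direction"), names(x))]
}

#' @rdname tidy.hla_assoc
#' @exportS3Method generics::glance
glance.hla_assoc <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x),
    n_significant = sum(x$p < 0.05, na.rm = TRUE),
    n_significant_corrected = sum(x$pc < 0.05, na.rm = TRUE),
    min_p = min(x$p, na.rm = TRUE))
}

#' Forest plot of an association scan
#'
#' Odds ratios with Woolf confidence intervals on a log scale, one row per
#' unit, coloured by direction of association.
#'
#' @param object An `hla_assoc` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hla_assoc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$unit <- factor(df$unit, levels = rev(df$unit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$unit,
                                   colour = .data$direction)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(predisposing = "#b2182b",
                                            protective = "#2166ac",
                                            none = "grey40")) +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-position residue association track
#'
#' Plots -log10(P) per scanned position for a residue scan, the track layout
#' used to display amino-acid fine mapping of the DRbeta and DQbeta chains.
#' Filled points mark predisposing residues, open points protective ones.
#'
#' @param results An `hla_assoc` tibble from [residue_carrier_scan()].
#' @param alpha Significance line drawn at `-log10(alpha)`.
#' @return A ggplot object.
#' @export
plot_residue_track <- function(results, alpha = 0.05) {
  stopifnot(all(c("position", "residue", "p") %in% names(results)))
  df <- tibble::as_tibble(results)
  df$label <- paste0(df$position, df$residue)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = -log10(.data$p))) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$direction,
                                     colour = .data$direction), size = 2) +
    ggplot2::scale_shape_manual(values = c(predisposing = 16,
                                           protective = 1, none = 4)) +
    ggplot2::scale_colour_manual(values = c(predisposing = "#b2182b",
                                            protective = "#2166ac",
                                            none = "grey50")) +
    ggplot2::labs(x = "mature-protein position", y = "-log10 P",
                  shape = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
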