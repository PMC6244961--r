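#' Plot a serum profile
#'
#' Normalized MFI per bead, coloured by positivity, with the cutoff drawn
#' as a dashed line.
#'
#' @param object A `serum_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.serum_profile <- function(object, ...) {
  cutoff <- attr(object, "cutoff") %||% 500
  df <- tibble::as_tibble(object)
  df$bead <- stats::reorder(df$bead, -df$normalized_mfi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bead, y = .data$normalized_mfi,
                                   fill = .data$positive)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::facet_grid(. ~ locus, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "normalized MFI",
                  title = sprintf("%s | %s, %s", df$serum_id[1],
                                  df$vendor[1], df$secondary[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot a panel variant summary
#'
#' Per-locus counts of beads positive for each conformational variant flag.
#'
#' @param object A [summarize_panel_variants()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variant_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$n_positive,
                                   fill = .data$flag)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "locus", y = "beads at or above cutoff",
                  fill = "variant flag") +
    ggplot2::theme_minimal()
}

#' Plot cross-vendor MFI agreement for one serum
#'
#' Scatter of per-antigen normalized MFI, LS against LC, one panel per
#' secondary antibody, with the identity line.
#'
#' @param object A [condition_quartet()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.condition_quartet <- function(object, ...) {
  df <- tidyr::pivot_wider(
    tibble::as_tibble(object)[c("secondary", "bead", "locus", "vendor",
                                "normalized_mfi")],
    names_from = "vendor", values_from = "normalized_mfi")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$LC, y = .data$LS,
                                   colour = .data$locus)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~secondary) +
    ggplot2::labs(x = "LC normalized MFI", y = "LS normalized MFI",
                  title = object$serum_id[1]) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
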