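#' Plot per-tissue Z-score densities
#'
#' Draws the shared-grid per-tissue density curves from [tissue_density()],
#' one facet strip per tissue ordered by median Z, with a dot at each
#' tissue's median and dashed lines at the trichotomization cuts.
#'
#' @param object a `tissue_density` from [tissue_density()].
#' @param z_cuts positions of the dashed cut lines (default -1 and +1).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tissue_density
#' @export
autoplot.tissue_density <- function(object, z_cuts = c(-1, 1), ...) {
  medians <- attr(object, "medians")
  ord <- medians$tissue_type[order(medians$median_z)]
  df <- dplyr::mutate(tibble::as_tibble(object),
                      tissue_type = factor(.data$tissue_type, levels = ord))
  med <- dplyr::mutate(medians,
                       tissue_type = factor(.data$tissue_type, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$density)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = z_cuts, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_point(data = med,
                        ggplot2::aes(x = .data$median_z, y = 0),
                        inherit.aes = FALSE, size = 1.5) +
    ggplot2::facet_wrap(~tissue_type, scales = "free_y") +
    ggplot2::labs(x = "global Z-score", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot per-tissue enrichment of biomarker-high samples
#'
#' Bar chart of the percent of biomarker-high samples per tissue, colored by
#' enrichment direction, with tissues reaching Fisher p < 0.05 marked.
#'
#' @param object a `tissue_enrichment` from [summarize_tissue_enrichment()].
#' @param alpha significance mark threshold (default 0.05).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tissue_enrichment
#' @export
autoplot.tissue_enrichment <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$tissue_type <- factor(df$tissue_type,
                           levels = rev(df$tissue_type))
  df$label <- ifelse(df$fisher_p < alpha, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue_type,
                                   y = 100 * .data$n_high / .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.4) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% samples with Z ≥ threshold",
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' Plot a cohort-eligibility funnel
#'
#' Bar chart of patients remaining after each eligibility stage.
#'
#' @param object a `funnel_report` from [apply_funnel()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot funnel_report
#' @export
autoplot.funnel_report <- function(object, ...) {
  df <- tibble::tibble(stage = factor(object$stage, levels = rev(object$stage)),
                       n_remaining = object$n_remaining)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_remaining)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_remaining), hjust = -0.1) +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = NULL, y = "patients remaining") +
    ggplot2::theme_minimal()
}
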