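# Diagnostic plots.

#' Scatterplot of hybrid versus parental expression by inheritance mode
#'
#' For one analysis group, plots each gene's log2 hybrid/Cornish ratio
#' against its log2 hybrid/White Leghorn ratio, coloured by assigned mode.
#' Conserved genes cluster at the origin, dominant genes hug one axis,
#' over-/under-dominant genes fall in the first/third quadrant. Genes with
#' any zero value are omitted.
#'
#' @param calls Call tibble from [classify_all()].
#' @param group Group to display (default `"MC"`).
#' @return A ggplot object.
#' @export
plot_inheritance <- function(calls, group = "MC") {
  d <- calls |>
    dplyr::filter(.data$group == !!group,
                  .data$p_cor > 0, .data$p_wl > 0, .data$h > 0) |>
    dplyr::mutate(mode = factor(.data$mode, levels = inheritance_modes()))
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$h / .data$p_wl),
                                  y = log2(.data$h / .data$p_cor),
                                  colour = .data$mode)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "log2(hybrid / WL parent)",
                  y = "log2(hybrid / Cor parent)",
                  colour = "mode", title = paste("Group", group)) +
    ggplot2::theme_minimal()
}

#' Plot an ASE regression fit
#'
#' Scatter of log2 White Leghorn versus log2 Cornish expression for the
#' parental and hybrid-allele strata, with the fitted least-squares lines
#' and the identity line for reference.
#'
#' @param object An `ase_fit` from [ase_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ase_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$log2_cor, y = .data$log2_wl)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = 2) +
    ggplot2::geom_abline(data = object$fits,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         colour = "firebrick") +
    ggplot2::facet_wrap(~stratum, scales = "free") +
    ggplot2::labs(x = "log2 Cor expression", y = "log2 WL expression",
                  title = paste("Dominant genes,", object$subset)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
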