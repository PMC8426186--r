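#' Plot cell-type enrichment scores
#'
#' Dot plot of the Wald z score per cell type, ordered by score, with
#' cell types passing the FDR threshold highlighted.
#'
#' @param object An `enrich_result` from [enrich_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrich_result
#' @export
autoplot.enrich_result <- function(object, ...) {
  level <- attr(object, "fdr_level") %||% 0.10
  df <- dplyr::filter(object, !is.na(.data$z))
  df$cell_type <- factor(df$cell_type, levels = rev(df$cell_type))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$cell_type,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#b2182b", `FALSE` = "grey30"),
      name = sprintf("FDR ≤ %.0f%%", 100 * level)) +
    ggplot2::labs(x = "enrichment z score", y = NULL,
                  title = "Cell-type enrichment of disease-associated genes") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.enrich_result
#' @export
plot_enrichment <- function(object, ...) autoplot.enrich_result(object, ...)

#' Plot composition effects as an LTSR-annotated heat map
#'
#' Tile map of posterior-mean effects per (factor level, cell type), with
#' tiles whose local true sign rate exceeds a threshold outlined.
#'
#' @param object A `composition_fit` from [fit_poisson_glmm()].
#' @param ltsr_threshold Outline tiles with LTSR above this value
#'   (default 0.9).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composition_fit
#' @export
autoplot.composition_fit <- function(object, ltsr_threshold = 0.9, ...) {
  df <- object$effects
  if (nrow(df) == 0) abort("fit contains no random effects to plot.")
  df$label <- paste(df$factor, df$level, sep = ": ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$label)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$post_mean), colour = "white") +
    ggplot2::geom_tile(data = df[df$ltsr > ltsr_threshold, , drop = FALSE],
                       fill = NA, colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "posterior\nmean") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf(
                    "Composition effects (outlined: LTSR > %.2f)", ltsr_threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.composition_fit
#' @export
plot_composition <- function(object, ...) autoplot.composition_fit(object, ...)
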