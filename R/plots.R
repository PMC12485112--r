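#' Plot a density-gradient fraction profile
#'
#' Fluorescence by fraction with the selected pooling window shaded.
#'
#' @param profile Data frame with `fraction`, `fluorescence`.
#' @param window Optional `c(start, end)` window to highlight.
#' @return A ggplot object.
#' @export
plot_fraction_profile <- function(profile, window = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$fraction, y = .data$fluorescence)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Fraction (top → bottom, 0.5 mL each)",
                  y = "Fluorescence (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(window))
    p <- p + ggplot2::annotate("rect", xmin = window[1] - 0.5,
                               xmax = window[2] + 0.5,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "red")
  p
}

#' @export
autoplot.fraction_sim <- function(object, window = NULL, ...) {
  plot_fraction_profile(object$profile, window = window)
}

#' Volcano plot of corona enrichment
#'
#' log2 fold change (LNP corona vs plasma control) against -log10 q, with
#' points colored by classification.
#'
#' @param object A `corona_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corona_enrichment <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_fc,
                                    y = -log10(.data$q_value),
                                    color = .data$class)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean_fmol_lnp), alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(enriched = "#c0392b",
                                           depleted = "#2980b9",
                                           not_significant = "grey60")) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_threshold")),
                        linetype = 2, color = "grey40") +
    ggplot2::labs(x = "log2 fold change (LNP corona / plasma)",
                  y = "-log10 q", size = "fmol (LNP)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Violin plot of peptide CV% by condition
#'
#' @param object A `corona_cv` object from [peptide_cv_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corona_cv <- function(object, ...) {
  ggplot2::ggplot(object$peptides,
                  ggplot2::aes(x = .data$condition, y = .data$cv_pct,
                               fill = .data$condition)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA,
                          show.legend = FALSE, fill = "white") +
    ggplot2::labs(x = NULL, y = "Peptide CV (%)") +
    ggplot2::theme_minimal()
}

#' Dunnett comparison plot
#'
#' Estimated differences vs control with pointwise significance flags.
#'
#' @param object A `corona_nested_anova` or `corona_rm_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corona_nested_anova <- function(object, ...) {
  dat <- object$comparisons
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$condition, y = .data$estimate,
                                    color = .data$significant)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 2 * .data$se,
      ymax = .data$estimate + 2 * .data$se)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::labs(x = NULL,
                  y = sprintf("Difference vs %s", object$control),
                  color = "Dunnett p < alpha") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.corona_rm_anova <- autoplot.corona_nested_anova
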