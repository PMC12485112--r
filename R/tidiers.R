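#' Tidy a corona enrichment result
#'
#' @param x A `corona_enrichment` object.
#' @param ... Unused.
#' @return The per-protein tibble (accession, log2 fold change, abundances,
#'   p, q, class).
#' @export
tidy.corona_enrichment <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "q_threshold") <- NULL
  attr(out, "lnp_only") <- NULL
  attr(out, "plasma_only") <- NULL
  out
}

#' Summarize a corona enrichment result
#'
#' @param x A `corona_enrichment` object.
#' @param ... Unused.
#' @return One-row tibble with tested / enriched / depleted /
#'   not-significant counts, the q threshold, and how many proteins were
#'   detected in only one condition.
#' @export
glance.corona_enrichment <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_enriched = sum(x$class == "enriched"),
    n_depleted = sum(x$class == "depleted"),
    n_not_significant = sum(x$class == "not_significant"),
    q_threshold = attr(x, "q_threshold"),
    n_lnp_only = length(attr(x, "lnp_only")),
    n_plasma_only = length(attr(x, "plasma_only")))
}

#' @rdname tidy.corona_enrichment
#' @export
tidy.corona_cv <- function(x, ...) x$peptides

#' @rdname glance.corona_enrichment
#' @export
glance.corona_cv <- function(x, ...) {
  tidyr::pivot_wider(x$medians, names_from = "condition",
                     values_from = c("median_cv_pct", "n_peptides"))
}

#' Tidy Dunnett comparisons of a nested ANOVA
#'
#' @param x A `corona_nested_anova` or `corona_rm_anova` object.
#' @param ... Unused.
#' @return The comparisons tibble (one row per condition vs control).
#' @export
tidy.corona_nested_anova <- function(x, ...) x$comparisons

#' @rdname tidy.corona_nested_anova
#' @export
tidy.corona_rm_anova <- function(x, ...) x$comparisons

#' Summarize a nested ANOVA fit
#'
#' @param x A `corona_nested_anova` or `corona_rm_anova` object.
#' @param ... Unused.
#' @return One-row tibble with the condition F statistic, degrees of
#'   freedom and p-value (plus the GG epsilon for the repeated-measures
#'   variant).
#' @export
glance.corona_nested_anova <- function(x, ...) {
  a <- x$anova[x$anova$term == "condition", ]
  tibble::tibble(statistic = a$statistic, df = a$df,
                 df_error = x$anova$df[2], p_value = a$p_value,
                 n_comparisons = nrow(x$comparisons))
}

#' @rdname glance.corona_nested_anova
#' @export
glance.corona_rm_anova <- function(x, ...) {
  a <- x$anova[x$anova$term == "condition", ]
  tibble::tibble(statistic = a$statistic, df = a$df,
                 df_error = x$anova$df[3], epsilon = x$epsilon,
                 p_value = a$p_value, n_comparisons = nrow(x$comparisons))
}
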