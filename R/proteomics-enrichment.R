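#' Corona enrichment analysis against the plasma-alone control
#'
#' Identifies proteins enriched in (or depleted from) the LNP protein corona
#' relative to a plasma-alone control separated and quantified identically.
#' Only proteins quantified in both conditions with at least two replicates
#' each are tested. Per protein:
#' `log2_fc = mean(log2 abundance, LNP) - mean(log2 abundance, plasma)`,
#' p from a Welch two-sample t-test on the log2 abundances, q from
#' Benjamini-Hochberg across all tested proteins. Classification:
#' `enriched` when `q < q_threshold` and `log2_fc > 0`, `depleted` when
#' `q < q_threshold` and `log2_fc < 0`, otherwise `not_significant`.
#'
#' Zero abundances are replaced by half the smallest nonzero abundance in
#' the same run before taking logs (reported via a message). Proteins
#' detected in only one condition are not assigned an infinite fold change;
#' they are reported separately in the `lnp_only` / `plasma_only`
#' attributes.
#'
#' @param abundances Data frame from [hi3_quantify()] (columns
#'   `protein_accession`, `condition`, `replicate_id`, `batch_id`,
#'   `abundance_fmol`).
#' @param q_threshold FDR threshold for classification (default 0.05).
#' @param conditions Length-2 character vector naming the corona and
#'   control conditions, in that order.
#' @param exclude Accessions to drop before testing (e.g. the spiked
#'   internal standard, which has zero true fold change by construction).
#' @return A tibble of class `corona_enrichment` with columns
#'   `protein_accession`, `log2_fc`, `mean_fmol_lnp`, `mean_fmol_plasma`,
#'   `p_value`, `q_value`, `class`; attributes `q_threshold`, `lnp_only`,
#'   `plasma_only`.
#' @export
enrichment_analysis <- function(abundances, q_threshold = 0.05,
                                conditions = c("LNP", "PLASMA"),
                                exclude = NULL) {
  req <- c("protein_accession", "condition", "replicate_id", "abundance_fmol")
  if (!all(req %in% names(abundances)))
    abort(paste("`abundances` must have columns:", paste(req, collapse = ", ")))
  tbl <- tibble::as_tibble(abundances)
  if (!"batch_id" %in% names(tbl)) tbl$batch_id <- "batch1"
  tbl <- filter(tbl, .data$condition %in% conditions,
                !.data$protein_accession %in% exclude)

  # floor zeros at half the smallest nonzero abundance of the same run
  n_zero <- sum(tbl$abundance_fmol == 0)
  if (n_zero > 0) {
    rlang::inform(sprintf(
      "enrichment_analysis: flooring %d zero abundance(s) at half the run minimum.",
      n_zero))
    tbl <- tbl |>
      group_by(.data$condition, .data$replicate_id, .data$batch_id) |>
      mutate(abundance_fmol = ifelse(
        .data$abundance_fmol == 0,
        min(.data$abundance_fmol[.data$abundance_fmol > 0]) / 2,
        .data$abundance_fmol)) |>
      ungroup()
  }

  wide <- tbl |>
    mutate(log2_abund = log2(.data$abundance_fmol)) |>
    group_by(.data$protein_accession) |>
    summarise(
      n_lnp = sum(.data$condition == conditions[1]),
      n_plasma = sum(.data$condition == conditions[2]),
      .groups = "drop")

  one_sided <- filter(wide, .data$n_lnp == 0 | .data$n_plasma == 0)
  lnp_only <- one_sided$protein_accession[one_sided$n_plasma == 0]
  plasma_only <- one_sided$protein_accession[one_sided$n_lnp == 0]
  testable <- filter(wide, .data$n_lnp >= 2, .data$n_plasma >= 2)
  skipped <- setdiff(wide$protein_accession,
                     c(testable$protein_accession, one_sided$protein_accession))
  if (length(skipped) > 0)
    warn(sprintf("Excluding %d protein(s) with < 2 replicates in a condition.",
                 length(skipped)))

  res <- tbl |>
    filter(.data$protein_accession %in% testable$protein_accession) |>
    mutate(log2_abund = log2(.data$abundance_fmol)) |>
    group_by(.data$protein_accession) |>
    summarise(
      log2_fc = mean(.data$log2_abund[.data$condition == conditions[1]]) -
        mean(.data$log2_abund[.data$condition == conditions[2]]),
      mean_fmol_lnp = mean(.data$abundance_fmol[.data$condition == conditions[1]]),
      mean_fmol_plasma = mean(.data$abundance_fmol[.data$condition == conditions[2]]),
      p_value = {
        a <- .data$log2_abund[.data$condition == conditions[1]]
        b <- .data$log2_abund[.data$condition == conditions[2]]
        tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
                 error = function(e) NA_real_)
      },
      .groups = "drop")

  n_degenerate <- sum(is.na(res$p_value))
  if (n_degenerate > 0)
    warn(sprintf("%d protein(s) had degenerate (constant) abundances; p set to 1.",
                 n_degenerate))
  res$p_value[is.na(res$p_value)] <- 1

  res <- res |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           class = case_when(
             .data$q_value < q_threshold & .data$log2_fc > 0 ~ "enriched",
             .data$q_value < q_threshold & .data$log2_fc < 0 ~ "depleted",
             TRUE ~ "not_significant")) |>
    arrange(desc(.data$log2_fc))

  structure(res,
            class = c("corona_enrichment", class(res)),
            q_threshold = q_threshold,
            lnp_only = lnp_only, plasma_only = plasma_only)
}

#' Compare fold-change and relative-abundance protein rankings
#'
#' Earlier corona studies ranked proteins by their relative abundance (%)
#' within the LNP sample alone; control-normalized fold change ranks them by
#' enrichment over the biofluid. This computes Pearson and Spearman
#' correlations between `log2_fc` and relative abundance, overall and
#' (optionally) within a caller-supplied protein subset such as the
#' apolipoproteins, to show how much the two views disagree.
#'
#' @param records A [enrichment_analysis()] result (or any data frame with
#'   `protein_accession` and `log2_fc`).
#' @param relative_abundance Data frame with columns `protein_accession`,
#'   `relative_abundance_pct`, or a named numeric vector.
#' @param subset Optional accession vector defining an additional scope.
#' @return Tibble with columns `scope`, `metric` (`pearson`/`spearman`),
#'   `estimate`, `n`.
#' @export
rank_comparison <- function(records, relative_abundance, subset = NULL) {
  if (is.numeric(relative_abundance) && !is.null(names(relative_abundance)))
    relative_abundance <- tibble::tibble(
      protein_accession = names(relative_abundance),
      relative_abundance_pct = unname(relative_abundance))
  shared <- inner_join(
    tibble::as_tibble(records)[, c("protein_accession", "log2_fc")],
    tibble::as_tibble(relative_abundance),
    by = "protein_accession")
  if (nrow(shared) < 3) abort("Need >= 3 proteins shared between rankings.")

  corr_rows <- function(dat, scope) {
    if (nrow(dat) < 3 || sd(dat$log2_fc) == 0 ||
        sd(dat$relative_abundance_pct) == 0) {
      warn(sprintf("Degenerate ranking in scope '%s'; correlations undefined.",
                   scope))
      return(tibble::tibble(scope = scope,
                            metric = c("pearson", "spearman"),
                            estimate = NA_real_, n = nrow(dat)))
    }
    tibble::tibble(
      scope = scope, metric = c("pearson", "spearman"),
      estimate = c(
        stats::cor(dat$log2_fc, dat$relative_abundance_pct),
        stats::cor(dat$log2_fc, dat$relative_abundance_pct, method = "spearman")),
      n = nrow(dat))
  }
  out <- corr_rows(shared, "all")
  if (!is.null(subset))
    out <- bind_rows(out, corr_rows(
      filter(shared, .data$protein_accession %in% subset), "subset"))
  out
}

#' Proteins consistently enriched across batches
#'
#' LC-MS/MS batches processed on different days vary in which low-abundance
#' corona proteins they detect; proteins classified as enriched in *every*
#' batch are the robust "hard corona" candidates. Returns per-protein
#' batch-enrichment counts with the consistent set as an attribute.
#'
#' @param batches List of [enrichment_analysis()] results (>= 1), one per
#'   batch.
#' @return Tibble with `protein_accession`, `n_batches_enriched`,
#'   `n_batches`, `consistent`; attribute `consistent_set` holds the
#'   accessions enriched in every batch.
#' @export
consistent_enrichment <- function(batches) {
  if (length(batches) == 0) abort("`batches` must contain at least one batch.")
  enriched_sets <- purrr::map(batches, function(b) {
    tibble::as_tibble(b) |> filter(.data$class == "enriched") |>
      pull("protein_accession")
  })
  all_acc <- sort(unique(unlist(
    purrr::map(batches, function(b) tibble::as_tibble(b)$protein_accession))))
  counts <- purrr::map_int(all_acc, function(a)
    sum(purrr::map_lgl(enriched_sets, function(s) a %in% s)))
  out <- tibble::tibble(
    protein_accession = all_acc,
    n_batches_enriched = counts,
    n_batches = length(batches),
    consistent = counts == length(batches)) |>
    arrange(desc(.data$n_batches_enriched), .data$protein_accession)
  structure(out, class = c("corona_consistency", class(out)),
            consistent_set = out$protein_accession[out$consistent])
}

#' EASE-score over-representation of annotation terms
#'
#' One-sided Fisher-exact over-representation of annotation terms (e.g. GO
#' categories or pathways) in a query protein set, using the conservative
#' EASE variant: one protein is removed from the query-term overlap before
#' computing the hypergeometric tail, penalizing terms supported by very few
#' proteins. A term passes when its overlap count reaches `min_count` and
#' its EASE p-value is at most `p_threshold` (the conventional DAVID-style
#' thresholds of 5 and 0.05 are the defaults).
#'
#' @param query Character vector of protein accessions (must be a subset of
#'   `background`).
#' @param annotations Data frame with columns `term_id`, `accession`
#'   mapping terms to proteins, or a named list of accession vectors.
#' @param background Character vector: the annotation universe.
#' @param min_count Minimum overlap count to pass (default 5).
#' @param p_threshold EASE p-value threshold to pass (default 0.05).
#' @return Tibble with `term_id`, `count`, `term_size`, `query_size`,
#'   `background_size`, `ease_p`, `fisher_p`, `pass`.
#' @export
ease_overrepresentation <- function(query, annotations, background,
                                    min_count = 5, p_threshold = 0.05) {
  if (is.list(annotations) && !is.data.frame(annotations))
    annotations <- tibble::tibble(
      term_id = rep(names(annotations), lengths(annotations)),
      accession = unlist(annotations, use.names = FALSE))
  if (!all(c("term_id", "accession") %in% names(annotations)))
    abort("`annotations` must have columns `term_id` and `accession`.")
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background))
    abort("`query` must be a subset of `background`.")

  outside <- setdiff(unique(annotations$accession), background)
  if (length(outside) > 0) {
    warn(sprintf(
      "Skipping %d annotation accession(s) outside the background space.",
      length(outside)))
    annotations <- filter(annotations, .data$accession %in% background)
  }

  N <- length(background)
  nq <- length(query)
  annotations |>
    tibble::as_tibble() |>
    distinct(.data$term_id, .data$accession) |>
    group_by(.data$term_id) |>
    summarise(term_size = dplyr::n(),
              count = sum(.data$accession %in% query), .groups = "drop") |>
    mutate(
      query_size = nq, background_size = N,
      fisher_p = ifelse(
        .data$count == 0, 1,
        phyper(.data$count - 1, .data$term_size, N - .data$term_size, nq,
               lower.tail = FALSE)),
      ease_p = ifelse(
        .data$count == 0, 1,
        phyper(.data$count - 2, .data$term_size, N - .data$term_size, nq,
               lower.tail = FALSE)),
      pass = .data$count >= min_count & .data$ease_p <= p_threshold) |>
    arrange(.data$ease_p) |>
    select("term_id", "count", "term_size", "query_size", "background_size",
           "ease_p", "fisher_p", "pass")
}
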