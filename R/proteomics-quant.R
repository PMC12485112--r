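#' Hi3 (top-3) absolute protein quantification
#'
#' Converts peptide-level intensities into absolute protein amounts using
#' the Hi3 approach: within each run (condition x technical replicate x
#' batch), a protein's abundance is
#' `spike_fmol * mean(top-3 peptide intensities of the protein) /
#'  mean(top-3 peptide intensities of the internal standard)`.
#' The internal standard (E. coli ClpB, accession P63284, spiked at 50 fmol
#' per 5 uL of digest by default) must be detected in every run. Proteins
#' with fewer than three usable peptides in a run are quantified from all
#' available peptides and flagged.
#'
#' Missing-intensity policy: within each condition x batch, peptides missing
#' (NA) in more than one technical replicate are excluded from
#' quantification for all runs of that condition x batch; remaining isolated
#' missing values simply do not contribute to that run. Ties in the top-3
#' selection are broken by `peptide_id` lexicographic order so results are
#' deterministic.
#'
#' @param peptides Data frame with columns `peptide_id`,
#'   `protein_accession`, `condition`, `replicate_id`, `batch_id`,
#'   `intensity` (a.u., `NA` for missing).
#' @param standard_accession Accession of the spiked internal standard.
#' @param spike_fmol Spiked amount (fmol).
#' @return Tibble with one row per protein x run: `protein_accession`,
#'   `condition`, `replicate_id`, `batch_id`, `abundance_fmol`,
#'   `n_peptides_used`, `flagged` (TRUE when < 3 peptides were available).
#' @export
hi3_quantify <- function(peptides, standard_accession = "P63284",
                         spike_fmol = 50) {
  req <- c("peptide_id", "protein_accession", "condition", "replicate_id",
           "batch_id", "intensity")
  if (!all(req %in% names(peptides)))
    abort(paste("`peptides` must have columns:", paste(req, collapse = ", ")))
  if (spike_fmol <= 0) abort("`spike_fmol` must be > 0.")

  tbl <- tibble::as_tibble(peptides)
  n_rep <- tbl |> distinct(.data$condition, .data$replicate_id) |>
    count(.data$condition) |> pull(n) |> max()

  # drop peptides missing in >1 replicate of a condition x batch
  dropped <- tbl |>
    group_by(.data$peptide_id, .data$condition, .data$batch_id) |>
    summarise(n_missing = sum(!is.finite(.data$intensity)), .groups = "drop") |>
    filter(.data$n_missing > 1)
  if (nrow(dropped) > 0) {
    rlang::inform(sprintf(
      "hi3_quantify: excluding %d peptide/condition/batch group(s) missing in >1 replicate.",
      nrow(dropped)))
    tbl <- anti_join(tbl, dropped,
                     by = c("peptide_id", "condition", "batch_id"))
  }
  tbl <- filter(tbl, is.finite(.data$intensity))

  top3_mean <- function(intensity, peptide_id) {
    ord <- order(-intensity, peptide_id)
    mean(intensity[ord][seq_len(min(3, length(intensity)))])
  }

  per_run <- tbl |>
    group_by(.data$protein_accession, .data$condition, .data$replicate_id,
             .data$batch_id) |>
    summarise(top3 = top3_mean(.data$intensity, .data$peptide_id),
              n_peptides_used = dplyr::n(), .groups = "drop")

  std <- per_run |>
    filter(.data$protein_accession == standard_accession) |>
    select("condition", "replicate_id", "batch_id", std_top3 = "top3")
  runs <- tbl |> distinct(.data$condition, .data$replicate_id, .data$batch_id)
  missing_runs <- anti_join(runs, std,
                            by = c("condition", "replicate_id", "batch_id"))
  if (nrow(missing_runs) > 0)
    abort(paste0("Internal standard `", standard_accession,
                 "` absent from run(s): ",
                 paste(missing_runs$condition, missing_runs$replicate_id,
                       missing_runs$batch_id, sep = "/", collapse = ", ")))

  per_run |>
    inner_join(std, by = c("condition", "replicate_id", "batch_id")) |>
    mutate(abundance_fmol = spike_fmol * (.data$top3 / .data$std_top3),
           flagged = .data$n_peptides_used < 3) |>
    select("protein_accession", "condition", "replicate_id", "batch_id",
           "abundance_fmol", "n_peptides_used", "flagged") |>
    arrange(.data$protein_accession, .data$condition, .data$batch_id,
            .data$replicate_id)
}

#' Peptide coefficient-of-variation summary
#'
#' Quantifies technical reproducibility of label-free quantification: for
#' each peptide within each condition (and batch), the CV% of its intensity
#' across technical replicates, `100 * sd / mean`, plus the per-condition
#' median CV% over peptides. Low median CV% (on the order of 10-20%)
#' indicates stable LC-MS/MS quantification.
#'
#' Peptides with fewer than two finite replicate intensities are excluded;
#' peptides with zero mean intensity are excluded with a warning.
#'
#' @inheritParams hi3_quantify
#' @return An object of class `corona_cv`: list with
#'   * `peptides` — tibble `peptide_id`, `protein_accession`, `condition`,
#'     `batch_id`, `cv_pct`, `n_replicates`;
#'   * `medians` — tibble `condition`, `median_cv_pct`, `n_peptides`.
#' @export
peptide_cv_summary <- function(peptides) {
  req <- c("peptide_id", "protein_accession", "condition", "replicate_id",
           "intensity")
  if (!all(req %in% names(peptides)))
    abort(paste("`peptides` must have columns:", paste(req, collapse = ", ")))
  tbl <- tibble::as_tibble(peptides)
  if (!"batch_id" %in% names(tbl)) tbl$batch_id <- "batch1"
  if (tbl |> distinct(.data$condition, .data$replicate_id) |>
      count(.data$condition) |> pull(n) |> min() < 2)
    abort("Need >= 2 replicates per condition.")

  per_pep <- tbl |>
    filter(is.finite(.data$intensity)) |>
    group_by(.data$peptide_id, .data$protein_accession, .data$condition,
             .data$batch_id) |>
    summarise(m = mean(.data$intensity), s = sd(.data$intensity),
              n_replicates = dplyr::n(), .groups = "drop") |>
    filter(.data$n_replicates >= 2)
  n_zero <- sum(per_pep$m == 0)
  if (n_zero > 0)
    warn(sprintf("Excluding %d peptide(s) with zero mean intensity.", n_zero))
  per_pep <- per_pep |>
    filter(.data$m > 0) |>
    mutate(cv_pct = 100 * .data$s / .data$m) |>
    select("peptide_id", "protein_accession", "condition", "batch_id",
           "cv_pct", "n_replicates")

  medians <- per_pep |>
    group_by(.data$condition) |>
    summarise(median_cv_pct = median(.data$cv_pct),
              n_peptides = dplyr::n(), .groups = "drop")

  structure(list(peptides = per_pep, medians = medians), class = "corona_cv")
}

#' @export
print.corona_cv <- function(x, ...) {
  cat("<corona_cv> median CV% by condition:\n")
  print(x$medians)
  invisible(x)
}
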