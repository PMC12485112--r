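#' Read a tidy per-fraction measurement table
#'
#' Expects one row per fraction with at least `fraction` and
#' `fluorescence` columns (optionally `absorbance`, `refractive_index`,
#' `replicate_id`). Checks that fraction indices are contiguous from 1 and
#' that fluorescence is non-negative.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_fraction_profile <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("fraction", "fluorescence") %in% names(tbl)))
    abort("Fraction table needs columns `fraction` and `fluorescence`.")
  idx <- sort(unique(tbl$fraction))
  if (!identical(as.integer(idx), seq_len(length(idx))))
    abort("Fraction indices must be contiguous from 1.")
  if (any(tbl$fluorescence < 0))
    abort("Negative fluorescence values; apply background handling upstream.")
  tbl
}

#' Read a tidy peptide-level intensity table
#'
#' @param path CSV or TSV file path (delimiter inferred from extension).
#' @return Tibble with `peptide_id`, `protein_accession`, `condition`,
#'   `replicate_id`, `batch_id`, `intensity`.
#' @export
read_peptide_table <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  tbl <- reader(path, show_col_types = FALSE)
  req <- c("peptide_id", "protein_accession", "condition", "replicate_id",
           "intensity")
  if (!all(req %in% names(tbl)))
    abort(paste("Peptide table needs columns:", paste(req, collapse = ", ")))
  if (!"batch_id" %in% names(tbl)) tbl$batch_id <- "batch1"
  dup <- tbl |>
    count(.data$peptide_id, .data$condition, .data$replicate_id,
          .data$batch_id) |>
    filter(n > 1)
  if (nrow(dup) > 0)
    abort("Duplicate (peptide, condition, replicate, batch) keys.")
  tbl
}

#' Read an annotation map
#'
#' Two-column TSV mapping annotation terms to protein accessions.
#'
#' @param path TSV file path with columns `term_id`, `accession`.
#' @return Tibble.
#' @export
read_annotation_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("term_id", "accession") %in% names(tbl)))
    abort("Annotation map needs columns `term_id` and `accession`.")
  tbl
}

#' Write a simulated FOV as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per channel; the sidecar records the channel order
#' and FOV metadata so channel mapping is explicit rather than inferred.
#'
#' @param fov A `fov_sim` object (or list with `channels` and `meta`).
#' @param path Output TIFF path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fov_tiff <- function(fov, path) {
  ch <- fov$channels
  scale <- max(unlist(lapply(ch, max)), 1)
  pages <- lapply(ch, function(m) m / scale)  # TIFF floats in [0,1]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(fov$meta, list(channel_order = names(ch), intensity_scale = scale))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF FOV written by [write_fov_tiff()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return List with `channels` (named matrices, original intensity scale)
#'   and `meta`.
#' @export
read_fov_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort("Missing channel-order sidecar JSON.")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) p * meta$intensity_scale)
  names(channels) <- meta$channel_order
  list(channels = channels,
       meta = meta[setdiff(names(meta), c("channel_order", "intensity_scale"))])
}
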