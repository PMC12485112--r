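#' Segment nuclei by global thresholding and connected components
#'
#' Thresholds the nuclei (Hoechst) channel with Otsu's method, labels
#' 8-connected components, and removes components smaller than
#' `min_area_px`. The surviving component count is the per-image nuclei
#' count used to normalize Cy5 signal.
#'
#' @param nuclei_channel Numeric matrix of nuclei-channel intensities.
#' @param min_area_px Minimum component area in pixels (default 50).
#' @return List with `labels` (integer matrix, 0 = background) and `count`.
#' @export
segment_nuclei <- function(nuclei_channel, min_area_px = 50) {
  if (length(nuclei_channel) == 0) abort("Empty channel.")
  if (all(nuclei_channel == 0)) {
    warn("Nuclei channel is uniformly zero; count = 0.")
    return(list(labels = matrix(0L, nrow(nuclei_channel), ncol(nuclei_channel)),
                count = 0L))
  }
  mask <- make_mask(nuclei_channel, method = "otsu")
  labels <- label_components(mask)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0])
    keep <- which(areas >= min_area_px)
    relabel <- integer(length(areas))
    relabel[keep] <- seq_along(keep)
    labels[labels > 0] <- relabel[labels[labels > 0]]
  }
  list(labels = labels, count = max(labels))
}

#' Label 8-connected components of a binary mask
#'
#' EBImage's `bwlabel()` uses 4-connectivity; diagonal-touching components
#' are merged here by union-find over labels adjacent under the four
#' diagonal shifts, yielding 8-connectivity labeling.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  labels <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  n <- max(labels)
  if (n <= 1) return(labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # collect diagonal adjacencies
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-nr, -nc]), as.vector(labels[-1, -1])),
    cbind(as.vector(labels[-1, -nc]), as.vector(labels[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  labels[labels > 0] <- relabel[labels[labels > 0]]
  labels
}

#' Create a binary mask from a fluorescence channel
#'
#' Thresholds a channel either with Otsu's method (256-level histogram over
#' the channel's range) or at a fixed value. Pixels at or above the
#' threshold are mask members. Thresholding should be applied with identical
#' parameters across all conditions of an experiment so masks are
#' comparable.
#'
#' @param channel Numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value when `method = "fixed"`.
#' @return Logical matrix.
#' @export
make_mask <- function(channel, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (length(channel) == 0) abort("Empty channel.")
  if (method == "fixed") {
    if (is.null(threshold)) abort("`threshold` required for fixed method.")
    return(channel >= threshold)
  }
  rng <- range(channel)
  if (rng[1] == rng[2])
    abort("Constant channel: Otsu threshold undefined; use method = \"fixed\".")
  t <- EBImage::otsu(EBImage::Image(channel), range = rng, levels = 256L)
  channel >= t
}

#' Clean a thresholded mask for morphological analysis
#'
#' Applies a 3x3 morphological opening (removing isolated noise-induced
#' foreground pixels) followed by hole filling (removing noise-induced
#' holes inside stained regions). Shot noise otherwise punches pinholes in
#' the membrane mask, and each pinhole carves a large void out of the
#' n-fold-eroded inner mask.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
clean_mask <- function(mask) {
  m <- EBImage::Image(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)))
  m <- EBImage::opening(m, EBImage::makeBrush(3, shape = "box"))
  m <- EBImage::fillHull(m)
  as.matrix(m) > 0
}

#' Total Cy5 signal per cell within the membrane mask
#'
#' Sums the cargo (Cy5) channel over the membrane mask and normalizes by
#' the nuclei count of the image, yielding the per-cell uptake measure.
#'
#' @param cy5 Numeric matrix, cargo channel.
#' @param membrane_mask Logical matrix from [make_mask()].
#' @param nuclei_count Positive integer from [segment_nuclei()].
#' @return Per-cell Cy5 signal (a.u./cell).
#' @export
quantify_uptake <- function(cy5, membrane_mask, nuclei_count) {
  if (nuclei_count < 1) abort("`nuclei_count` must be >= 1; exclude this FOV.")
  stopifnot(all(dim(cy5) == dim(membrane_mask)))
  sum(cy5[membrane_mask]) / nuclei_count
}

#' Partition a cell mask into inner core and outer rim by erosion
#'
#' The inner mask is the n-fold morphological erosion of the membrane mask
#' with a full 3x3 (8-connected) structuring element; the outer mask is the
#' exclusive disjunction of the membrane mask and the inner mask. Pixels
#' outside the image count as background, so a mask touching the border is
#' eroded there too. Signal in the outer rim is attributed to LNPs
#' associated with the cell surface rather than internalized.
#'
#' @param membrane_mask Logical matrix.
#' @param n Erosion iterations (default 10).
#' @return List with logical matrices `inner` and `outer`
#'   (`inner | outer == membrane_mask`, `inner & outer` empty).
#' @export
erosion_partition <- function(membrane_mask, n = 10) {
  if (n < 1) abort("`n` must be >= 1.")
  m <- matrix(as.numeric(membrane_mask > 0), nrow(membrane_mask),
              ncol(membrane_mask))
  brush <- EBImage::makeBrush(3, shape = "box")
  for (i in seq_len(n)) {
    padded <- matrix(0, nrow(m) + 2, ncol(m) + 2)
    padded[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    eroded <- as.matrix(EBImage::erode(padded, brush))
    m <- eroded[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  }
  inner <- m > 0
  list(inner = inner, outer = (membrane_mask > 0) & !inner)
}

#' Fraction of in-mask Cy5 signal located in the outer rim
#'
#' @param cy5 Numeric matrix, cargo channel.
#' @param membrane_mask,outer_mask Logical matrices ([erosion_partition()]).
#' @return Fraction in `[0, 1]`.
#' @export
outer_signal_fraction <- function(cy5, membrane_mask, outer_mask) {
  total <- sum(cy5[membrane_mask > 0])
  if (total <= 0) abort("Zero in-mask Cy5 signal; exclude this FOV.")
  sum(cy5[outer_mask > 0]) / total
}

#' Lysosome-co-localized Cy5 signal per cell
#'
#' Sums the cargo channel over the lysosome mask (LysoTracker channel) and
#' normalizes by nuclei count — a proxy for LNP trafficking to lysosomes.
#'
#' @param cy5 Numeric matrix, cargo channel.
#' @param lysosome_mask Logical matrix from [make_mask()].
#' @param nuclei_count Positive integer.
#' @return Co-localized signal (a.u./cell).
#' @export
lysosome_colocalization <- function(cy5, lysosome_mask, nuclei_count) {
  if (nuclei_count < 1) abort("`nuclei_count` must be >= 1; exclude this FOV.")
  sum(cy5[lysosome_mask > 0]) / nuclei_count
}

#' Measure one field of view end to end
#'
#' Convenience wrapper running the full per-FOV quantification: nuclei
#' segmentation, membrane (or lysosome) masking, background subtraction of
#' the Cy5 channel, per-cell uptake, erosion partition and outer fraction,
#' and (when a lysosome channel is present) lysosomal co-localization.
#' Masks are cleaned with [clean_mask()] before morphological analysis.
#' The Cy5 background is estimated as the median intensity outside the
#' membrane mask and subtracted (without clipping, so zero-mean noise
#' cancels in the in-mask sums) so that per-cell values reflect punctate
#' signal rather than camera offset.
#'
#' @param fov A `fov_sim` object or a list with `channels` (named matrices
#'   `nuclei`, `membrane`, `cy5`, optionally `lysosome`) and `meta`.
#' @param erosion_n Erosion iterations for the inner/outer partition.
#' @param min_area_px Minimum nucleus area; defaults to half the area of
#'   the simulated nucleus when the FOV carries its config, else 50.
#' @param mask_method,mask_threshold Passed to [make_mask()] for the
#'   membrane and lysosome channels.
#' @return One-row tibble: `condition`, `biological_replicate`,
#'   `technical_replicate`, `fov_index`, `nuclei_count`, `cy5_per_cell`,
#'   `outer_fraction`, `lyso_coloc_per_cell` (NA without a lysosome
#'   channel), `excluded` plus `exclude_reason`.
#' @export
measure_fov <- function(fov, erosion_n = 10, min_area_px = NULL,
                        mask_method = "otsu", mask_threshold = NULL) {
  ch <- fov$channels
  meta <- fov$meta %||% list(condition = NA_character_,
                             biological_replicate = NA_character_,
                             technical_replicate = NA_character_,
                             fov_index = NA_integer_)
  if (is.null(min_area_px)) {
    cfg <- fov$truth$config
    min_area_px <- if (!is.null(cfg)) round(pi * (cfg$nucleus_radius / 2)^2) else 50
  }
  base_row <- tibble::tibble(
    condition = meta$condition,
    biological_replicate = meta$biological_replicate,
    technical_replicate = meta$technical_replicate,
    fov_index = meta$fov_index)

  seg <- segment_nuclei(ch$nuclei, min_area_px = min_area_px)
  if (seg$count == 0) {
    warn("FOV excluded: no nuclei detected.")
    return(base_row |> mutate(nuclei_count = 0L, cy5_per_cell = NA_real_,
                              outer_fraction = NA_real_,
                              lyso_coloc_per_cell = NA_real_,
                              excluded = TRUE, exclude_reason = "no_nuclei"))
  }
  mem <- clean_mask(make_mask(ch$membrane, method = mask_method,
                              threshold = mask_threshold))
  bg <- median(ch$cy5[!mem])
  cy5 <- ch$cy5 - bg  # no clipping: in-mask noise averages to zero
  if (sum(cy5[mem]) <= 0) {
    warn("FOV excluded: no in-mask Cy5 signal.")
    return(base_row |> mutate(nuclei_count = seg$count, cy5_per_cell = NA_real_,
                              outer_fraction = NA_real_,
                              lyso_coloc_per_cell = NA_real_,
                              excluded = TRUE, exclude_reason = "no_signal"))
  }
  part <- erosion_partition(mem, n = erosion_n)
  lyso <- if (!is.null(ch$lysosome)) {
    lyso_mask <- clean_mask(make_mask(ch$lysosome, method = mask_method,
                                      threshold = mask_threshold))
    lysosome_colocalization(cy5, lyso_mask, seg$count)
  } else NA_real_

  base_row |>
    mutate(nuclei_count = seg$count,
           cy5_per_cell = quantify_uptake(cy5, mem, seg$count),
           outer_fraction = outer_signal_fraction(cy5, mem, part$outer),
           lyso_coloc_per_cell = lyso,
           excluded = FALSE, exclude_reason = NA_character_)
}

#' Aggregate FOV measurements into technical and biological replicates
#'
#' FOV-level values are mean-aggregated to one value per technical
#' replicate (three FOVs per technical replicate in a typical acquisition),
#' and technical-replicate values are mean-aggregated to one value per
#' biological replicate. Both levels are returned so nested statistics can
#' use the technical level within biological replicates. Excluded FOVs are
#' dropped; empty groups are dropped with a warning.
#'
#' @param measurements Tibble of [measure_fov()] rows.
#' @param values Character vector of measurement columns to aggregate.
#' @return List of class `fov_replicates` with tibbles `technical` and
#'   `biological`.
#' @export
aggregate_replicates <- function(measurements,
                                 values = c("cy5_per_cell", "outer_fraction",
                                            "lyso_coloc_per_cell")) {
  tbl <- tibble::as_tibble(measurements)
  if ("excluded" %in% names(tbl)) {
    n_excl <- sum(tbl$excluded)
    if (n_excl > 0)
      warn(sprintf("Dropping %d excluded FOV(s) before aggregation.", n_excl))
    tbl <- filter(tbl, !.data$excluded)
  }
  if (nrow(tbl) == 0) abort("No retained FOVs to aggregate.")
  values <- intersect(values, names(tbl))
  technical <- tbl |>
    group_by(.data$condition, .data$biological_replicate,
             .data$technical_replicate) |>
    summarise(across(all_of(values), \(x) mean(x, na.rm = TRUE)),
              n_fov = dplyr::n(), .groups = "drop")
  biological <- technical |>
    group_by(.data$condition, .data$biological_replicate) |>
    summarise(across(all_of(values), mean),
              n_technical = dplyr::n(), .groups = "drop")
  structure(list(technical = technical, biological = biological),
            class = "fov_replicates")
}

#' @export
print.fov_replicates <- function(x, ...) {
  cat("<fov_replicates>", nrow(x$technical), "technical /",
      nrow(x$biological), "biological replicate rows\n")
  print(x$biological)
  invisible(x)
}
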