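#' Configuration for simulated multi-channel fields of view
#'
#' Describes the acquisition geometry of a per-cell uptake experiment: a
#' nuclei channel (bright disks), a cytoplasmic membrane-stain channel
#' (filled cell disks), an optional lysosome channel (small disks inside the
#' cells), and a Cy5 cargo channel containing diffraction-blurred puncta
#' placed in three compartments — the cell interior (`inner`), a rim band of
#' width `rim_width` pixels at the cell edge (`outer`, modelling LNPs
#' associated with the outer membrane), and lysosomes (`lyso`). Punctum
#' counts per cell are Poisson with the given per-compartment rates. Shot
#' noise is a Gaussian approximation to Poisson noise
#' (sd = `photon_noise_scale * sqrt(intensity)`).
#'
#' `rim_width` defaults to 10 px so the placement band matches the default
#' 10-fold erosion depth used by [erosion_partition()]. Because n-fold 3x3
#' erosion is a Chebyshev-metric operation, a disk eroded n times loses a
#' Euclidean margin of up to `n * sqrt(2)` px at the box corners; inner
#' puncta and lysosomes are therefore placed at radius
#' `< cell_radius - sqrt(2) * rim_width` (minus a small blur margin) so the
#' erosion partition classifies placements consistently with the recorded
#' compartment truth.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param n_cells Number of non-overlapping cells to place.
#' @param nucleus_radius,cell_radius Disk radii in px (`cell_radius` must
#'   exceed `nucleus_radius`).
#' @param rim_width Width of the outer rim band, px.
#' @param puncta_per_cell_inner,puncta_per_cell_outer,puncta_per_cell_lyso
#'   Poisson rates of puncta per cell by compartment.
#' @param lysosomes_per_cell Lysosomes per cell (radius-2 disks).
#' @param punctum_amplitude Integrated intensity of one punctum (a.u.).
#' @param psf_sigma Gaussian PSF sigma, px.
#' @param photon_noise_scale Shot-noise scale (0 disables noise).
#' @param background Flat background level (a.u.).
#' @param seed Integer seed.
#' @return A validated `fov_sim_config` list.
#' @export
fov_sim_config <- function(image_shape = c(192, 192), n_cells = 6,
                           nucleus_radius = 6, cell_radius = 24,
                           rim_width = 10,
                           puncta_per_cell_inner = 5,
                           puncta_per_cell_outer = 1,
                           puncta_per_cell_lyso = 2,
                           lysosomes_per_cell = 8,
                           punctum_amplitude = 500,
                           psf_sigma = 1.2, photon_noise_scale = 1,
                           background = 5, seed = 1L) {
  if (cell_radius <= nucleus_radius)
    abort("`cell_radius` must exceed `nucleus_radius`.")
  rates <- c(puncta_per_cell_inner, puncta_per_cell_outer, puncta_per_cell_lyso)
  if (any(rates < 0)) abort("Puncta rates must be >= 0.")
  if (rim_width < 1 || sqrt(2) * rim_width + 3 >= cell_radius)
    abort("`rim_width` too large for `cell_radius`: need sqrt(2)*rim_width + 3 < cell_radius so an inner placement region exists.")
  if (puncta_per_cell_lyso > 0 && lysosomes_per_cell < 1)
    abort("Cannot place lysosomal puncta with `lysosomes_per_cell` = 0.")
  structure(
    list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
         nucleus_radius = nucleus_radius, cell_radius = cell_radius,
         rim_width = rim_width,
         puncta_per_cell_inner = puncta_per_cell_inner,
         puncta_per_cell_outer = puncta_per_cell_outer,
         puncta_per_cell_lyso = puncta_per_cell_lyso,
         lysosomes_per_cell = as.integer(lysosomes_per_cell),
         punctum_amplitude = punctum_amplitude,
         psf_sigma = psf_sigma, photon_noise_scale = photon_noise_scale,
         background = background, seed = as.integer(seed)),
    class = "fov_sim_config")
}

# Add a filled disk of `value` to matrix `m` at (row, col) center.
.add_disk <- function(m, row, col, radius, value) {
  r0 <- max(1, floor(row - radius)); r1 <- min(nrow(m), ceiling(row + radius))
  c0 <- max(1, floor(col - radius)); c1 <- min(ncol(m), ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  patch <- m[rr, cc]
  patch[d2 <= radius^2] <- value
  m[rr, cc] <- patch
  m
}

# Non-overlapping cell centers by rejection sampling; errors if geometry
# cannot be honored.
.place_cells <- function(shape, n_cells, cell_radius) {
  margin <- cell_radius + 2
  if (2 * margin >= min(shape))
    abort("Image too small for the requested `cell_radius`.")
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < n_cells) {
    tries <- tries + 1
    if (tries > 5000)
      abort(sprintf("Could not place %d non-overlapping cells of radius %g in a %dx%d image.",
                    n_cells, cell_radius, shape[1], shape[2]))
    cand <- c(runif(1, margin, shape[1] - margin),
              runif(1, margin, shape[2] - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2, byrow = TRUE))^2)) >
            2 * cell_radius + 1)) {
      centers <- rbind(centers, cand)
    }
  }
  centers
}

# Uniform point in the annulus [r_in, r_out) around (row, col).
.annulus_point <- function(row, col, r_in, r_out) {
  r <- sqrt(runif(1, r_in^2, r_out^2))
  a <- runif(1, 0, 2 * pi)
  c(row + r * sin(a), col + r * cos(a))
}

#' Simulate one multi-channel field of view with ground truth
#'
#' @param cfg A [fov_sim_config()].
#' @param condition,biological_replicate,technical_replicate,fov_index
#'   Metadata carried on the result (used by [measure_fov()] /
#'   [aggregate_replicates()]).
#' @return An object of class `fov_sim`: a list with
#'   * `channels` — named list of numeric matrices `nuclei`, `membrane`,
#'     `lysosome` (present when `lysosomes_per_cell > 0`), `cy5`;
#'   * `meta` — the metadata fields;
#'   * `truth` — list with `n_cells`, `cell_centers`, `placements` (tibble:
#'     `cell`, `compartment`, `row`, `col`, `amplitude`), per-compartment
#'     counts, `per_cell_signal` (total placed amplitude / n_cells),
#'     `outer_fraction` (amplitude-weighted), `coloc_per_cell`, and the
#'     config.
#' @export
sim_fov <- function(cfg, condition = "sim", biological_replicate = "bio1",
                    technical_replicate = "tech1", fov_index = 1L) {
  stopifnot(inherits(cfg, "fov_sim_config"))
  shape <- cfg$image_shape
  with_seed(derive_seed(cfg$seed, paste0("fov", fov_index)), {
    centers <- .place_cells(shape, cfg$n_cells, cfg$cell_radius)

    nuc <- matrix(0, shape[1], shape[2])
    mem <- matrix(0, shape[1], shape[2])
    lyso_ch <- matrix(0, shape[1], shape[2])
    cy5 <- matrix(0, shape[1], shape[2])

    lyso_centers <- list()
    for (i in seq_len(cfg$n_cells)) {
      mem <- .add_disk(mem, centers[i, 1], centers[i, 2], cfg$cell_radius, 30)
      nuc <- .add_disk(nuc, centers[i, 1], centers[i, 2], cfg$nucleus_radius, 100)
      if (cfg$lysosomes_per_cell > 0) {
        pts <- t(replicate(cfg$lysosomes_per_cell, .annulus_point(
          centers[i, 1], centers[i, 2], 0,
          cfg$cell_radius - sqrt(2) * cfg$rim_width - 3)))
        for (j in seq_len(nrow(pts)))
          lyso_ch <- .add_disk(lyso_ch, pts[j, 1], pts[j, 2], 2, 80)
        lyso_centers[[i]] <- pts
      }
    }

    placements <- list()
    for (i in seq_len(cfg$n_cells)) {
      counts <- c(inner = rpois(1, cfg$puncta_per_cell_inner),
                  outer = rpois(1, cfg$puncta_per_cell_outer),
                  lyso = rpois(1, cfg$puncta_per_cell_lyso))
      pts <- list()
      if (counts["inner"] > 0)
        pts$inner <- t(replicate(counts["inner"], .annulus_point(
          centers[i, 1], centers[i, 2], 0,
          cfg$cell_radius - sqrt(2) * cfg$rim_width - 2)))
      if (counts["outer"] > 0)
        pts$outer <- t(replicate(counts["outer"], .annulus_point(
          centers[i, 1], centers[i, 2],
          cfg$cell_radius - cfg$rim_width + 1, cfg$cell_radius - 1)))
      if (counts["lyso"] > 0) {
        pick <- sample.int(cfg$lysosomes_per_cell, counts["lyso"], replace = TRUE)
        pts$lyso <- lyso_centers[[i]][pick, , drop = FALSE]
      }
      for (comp in names(pts)) {
        p <- pts[[comp]]
        placements[[length(placements) + 1]] <- tibble::tibble(
          cell = i, compartment = comp,
          row = p[, 1], col = p[, 2],
          amplitude = cfg$punctum_amplitude)
      }
    }
    placements <- if (length(placements)) bind_rows(placements) else
      tibble::tibble(cell = integer(), compartment = character(),
                     row = numeric(), col = numeric(), amplitude = numeric())

    if (nrow(placements) > 0) {
      for (k in seq_len(nrow(placements))) {
        r <- round(placements$row[k]); c <- round(placements$col[k])
        r <- min(max(r, 1), shape[1]); c <- min(max(c, 1), shape[2])
        cy5[r, c] <- cy5[r, c] + placements$amplitude[k]
      }
      cy5 <- as.matrix(EBImage::gblur(cy5, sigma = cfg$psf_sigma))
    }
    cy5 <- cy5 + cfg$background
    if (cfg$photon_noise_scale > 0) {
      noisy <- function(m) pmax(m + rnorm(length(m), sd = cfg$photon_noise_scale *
                                            sqrt(pmax(m, 0))), 0)
      cy5 <- matrix(noisy(cy5), shape[1], shape[2])
      nuc <- matrix(noisy(nuc + 1), shape[1], shape[2])
      mem <- matrix(noisy(mem + 1), shape[1], shape[2])
      if (cfg$lysosomes_per_cell > 0)
        lyso_ch <- matrix(noisy(lyso_ch + 1), shape[1], shape[2])
    }

    counts_by <- placements |>
      count(.data$compartment) |>
      tidyr::complete(compartment = c("inner", "outer", "lyso"),
                      fill = list(n = 0L))
    total_amp <- sum(placements$amplitude)
    outer_amp <- sum(placements$amplitude[placements$compartment == "outer"])
    lyso_amp <- sum(placements$amplitude[placements$compartment == "lyso"])

    channels <- list(nuclei = nuc, membrane = mem, cy5 = cy5)
    if (cfg$lysosomes_per_cell > 0) channels$lysosome <- lyso_ch

    structure(list(
      channels = channels,
      meta = list(condition = condition,
                  biological_replicate = biological_replicate,
                  technical_replicate = technical_replicate,
                  fov_index = as.integer(fov_index)),
      truth = list(
        n_cells = cfg$n_cells, cell_centers = centers,
        placements = placements,
        counts = setNames(counts_by$n, counts_by$compartment),
        per_cell_signal = total_amp / cfg$n_cells,
        outer_fraction = if (total_amp > 0) outer_amp / total_amp else NA_real_,
        coloc_per_cell = lyso_amp / cfg$n_cells,
        config = cfg)),
      class = "fov_sim")
  })
}

#' @export
print.fov_sim <- function(x, ...) {
  cat("<fov_sim>", paste(dim(x$channels$cy5), collapse = "x"), "px,",
      x$truth$n_cells, "cells, puncta:",
      paste(names(x$truth$counts), x$truth$counts, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate per-event flow-cytometry intensities with ground truth
#'
#' Control events are Normal(`control_mean`, `control_sd`); treated events
#' are shifted up by `treated_shift` (a location-shift model of increased
#' per-cell uptake). The ground truth records the exact fraction of treated
#' events above the empirical control gate at `gate_quantile`, i.e. the
#' quantity [flow_gate()] estimates.
#'
#' @param n_events Events per sample (>= 1000).
#' @param control_mean,control_sd Control population parameters (a.u.).
#' @param treated_shift Additive shift of the treated population (a.u.).
#' @param gate_quantile Control quantile defining the positive gate.
#' @param seed Integer seed.
#' @return An object of class `flow_sim`: list with `events` (tibble:
#'   `group` in `control`/`treated`, `intensity`) and `truth` (list with
#'   `gate_threshold`, `true_pct_positive`, and the parameters).
#' @export
sim_flow_sample <- function(n_events = 10000, control_mean = 100,
                            control_sd = 20, treated_shift = 60,
                            gate_quantile = 0.995, seed = 1L) {
  if (n_events < 1000) abort("`n_events` must be >= 1000.")
  if (control_sd <= 0) abort("`control_sd` must be > 0.")
  with_seed(derive_seed(seed, "flow"), {
    control <- rnorm(n_events, control_mean, control_sd)
    treated <- rnorm(n_events, control_mean + treated_shift, control_sd)
    gate <- unname(quantile(control, gate_quantile, type = 7))
    structure(list(
      events = tibble::tibble(
        group = rep(c("control", "treated"), each = n_events),
        intensity = c(control, treated)),
      truth = list(gate_threshold = gate,
                   true_pct_positive = 100 * mean(treated > gate),
                   gate_quantile = gate_quantile,
                   control_mean = control_mean, control_sd = control_sd,
                   treated_shift = treated_shift, seed = as.integer(seed))),
      class = "flow_sim")
  })
}
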