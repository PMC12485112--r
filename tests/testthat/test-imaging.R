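disk_image <- function(size, centers, radius, value = 100, bg = 1) {
  m <- matrix(bg, size, size)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(size) - centers[k, 1])^2,
                (seq_len(size) - centers[k, 2])^2, "+")
    m[d2 <= radius^2] <- value
  }
  m
}

test_that("nuclei segmentation counts disjoint, merged and absent nuclei", {
  expect_warning(res0 <- segment_nuclei(matrix(0, 32, 32)), "zero")
  expect_equal(res0$count, 0L)

  three <- disk_image(96, rbind(c(20, 20), c(20, 70), c(70, 45)), 8)
  expect_equal(segment_nuclei(three, min_area_px = 20)$count, 3)

  merged <- disk_image(96, rbind(c(40, 40), c(40, 50)), 8)
  expect_equal(segment_nuclei(merged, min_area_px = 20)$count, 1)

  # min-area filter removes debris-sized components
  debris <- disk_image(96, rbind(c(20, 20)), 8)
  debris[70, 70] <- 200
  expect_equal(segment_nuclei(debris, min_area_px = 20)$count, 1)
})

test_that("component labeling is 8-connected", {
  m <- matrix(0, 6, 6)
  m[1:2, 1:2] <- 1
  m[3:4, 3:4] <- 1  # touches only diagonally
  lab <- label_components(m)
  expect_equal(max(lab), 1L)
  m[6, 6] <- 1      # isolated pixel: separate component
  expect_equal(max(label_components(m)), 2L)
})

test_that("make_mask matches a brute-force Otsu oracle and handles edge cases", {
  img <- matrix(1, 40, 40)
  expect_true(all(make_mask(img, method = "fixed", threshold = 0)))
  expect_error(make_mask(img, method = "otsu"), "Constant")

  withr::with_seed(8, {
    bimodal <- matrix(c(rnorm(800, 10, 2), rnorm(800, 200, 10)), 40, 40)
  })
  mask <- make_mask(bimodal)
  expect_identical(mask, bimodal >= otsu_oracle(bimodal))
  expect_identical(unname(mask), unname(bimodal > 100))  # separates the modes

  # idempotence on a binary image
  bin <- matrix(as.numeric(bimodal > 100), 40, 40)
  expect_identical(make_mask(bin), bin >= otsu_oracle(bin))
})

test_that("uptake quantification is exact, linear, and guards nuclei count", {
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  cy5 <- matrix(0, 20, 20)
  expect_equal(quantify_uptake(cy5, mask, 4), 0)
  cy5[mask] <- 2
  expect_equal(quantify_uptake(cy5, mask, 4), 50)  # 200 / 4
  expect_equal(quantify_uptake(2 * cy5, mask, 4), 100)
  expect_error(quantify_uptake(cy5, mask, 0), "exclude")
})

test_that("erosion partition reproduces the square and single-pixel cases", {
  sq <- matrix(FALSE, 40, 40); sq[6:35, 6:35] <- TRUE
  p <- erosion_partition(sq, n = 10)
  expect_equal(sum(p$inner), 100)   # centered 10x10 core
  expect_equal(sum(p$outer), 800)
  expect_true(all(p$inner[16:25, 16:25]))

  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  p1 <- erosion_partition(px, n = 10)
  expect_equal(sum(p1$inner), 0)
  expect_identical(p1$outer, px)
})

test_that("erosion partition equals the Chebyshev distance-transform oracle", {
  withr::with_seed(12, {
    for (i in 1:40) {
      mask <- random_blob_mask(48)
      n <- sample(c(2, 5, 10), 1)
      p <- erosion_partition(mask, n = n)
      # partition invariants
      expect_identical(p$inner | p$outer, mask)
      expect_false(any(p$inner & p$outer))
      # inner <=> Chebyshev distance to background > n
      expect_identical(p$inner, chebyshev_dt(mask) > n)
    }
  })
})

test_that("outer signal fraction follows the pixel-count ratio and partitions", {
  sq <- matrix(FALSE, 40, 40); sq[6:35, 6:35] <- TRUE
  p <- erosion_partition(sq, n = 10)
  cy5 <- matrix(0, 40, 40); cy5[sq] <- 3
  expect_equal(outer_signal_fraction(cy5, sq, p$outer), 800 / 900,
               tolerance = 1e-12)
  inner_frac <- sum(cy5[p$inner]) / sum(cy5[sq])
  expect_equal(outer_signal_fraction(cy5, sq, p$outer) + inner_frac, 1,
               tolerance = 1e-12)

  cy5in <- matrix(0, 40, 40); cy5in[p$inner] <- 5
  expect_equal(outer_signal_fraction(cy5in, sq, p$outer), 0)
  expect_error(outer_signal_fraction(matrix(0, 40, 40), sq, p$outer), "Zero")
})

test_that("lysosome colocalization is disjoint-safe and mask-monotone", {
  cy5 <- matrix(0, 30, 30); cy5[5:10, 5:10] <- 4
  lyso <- matrix(FALSE, 30, 30); lyso[20:25, 20:25] <- TRUE
  expect_equal(lysosome_colocalization(cy5, lyso, 3), 0)
  grown <- lyso; grown[5:10, 5:10] <- TRUE
  expect_gte(lysosome_colocalization(cy5, grown, 3),
             lysosome_colocalization(cy5, lyso, 3))
  expect_error(lysosome_colocalization(cy5, lyso, 0), "exclude")
})

test_that("per-cell signal is invariant under padding with background", {
  fov <- sim_fov(fov_sim_config(photon_noise_scale = 0, background = 0,
                                seed = 14))
  mask <- clean_mask(make_mask(fov$channels$membrane, "fixed", threshold = 15))
  v1 <- quantify_uptake(fov$channels$cy5, mask, fov$truth$n_cells)
  pad <- function(m, w) {
    out <- matrix(0, nrow(m) + 2 * w, ncol(m) + 2 * w)
    out[w + seq_len(nrow(m)), w + seq_len(ncol(m))] <- m
    out
  }
  v2 <- quantify_uptake(pad(fov$channels$cy5, 16), pad(mask, 16) > 0,
                        fov$truth$n_cells)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("replicate aggregation means FOVs then technical replicates", {
  meas <- tibble::tibble(
    condition = "c", biological_replicate = "b1",
    technical_replicate = rep(c("t1", "t2"), c(3, 1)),
    fov_index = 1:4,
    cy5_per_cell = c(10, 20, 30, 7),
    outer_fraction = c(0.1, 0.2, 0.3, 0.4),
    lyso_coloc_per_cell = NA_real_,
    excluded = FALSE, exclude_reason = NA_character_)
  agg <- aggregate_replicates(meas)
  expect_equal(agg$technical$cy5_per_cell, c(20, 7))
  expect_equal(agg$biological$cy5_per_cell, mean(c(20, 7)))

  # permutation invariance
  agg2 <- aggregate_replicates(meas[sample(4), ])
  expect_equal(dplyr::arrange(agg2$technical, technical_replicate),
               dplyr::arrange(agg$technical, technical_replicate))

  # excluded FOVs are dropped with a warning
  meas$excluded[2] <- TRUE
  expect_warning(agg3 <- aggregate_replicates(meas), "excluded")
  expect_equal(agg3$technical$cy5_per_cell[1], mean(c(10, 30)))
})

test_that("measured per-cell signal tracks ground truth on noisy FOVs", {
  fov <- sim_fov(fov_sim_config(seed = 5))
  m <- measure_fov(fov)
  expect_equal(m$nuclei_count, fov$truth$n_cells)
  expect_equal(m$cy5_per_cell, fov$truth$per_cell_signal, tolerance = 0.12)
  expect_lt(abs(m$outer_fraction - fov$truth$outer_fraction), 0.05)
  expect_false(m$excluded)
})

test_that("FOV TIFF round-trip preserves channels and metadata", {
  fov <- sim_fov(fov_sim_config(image_shape = c(96L, 96L), n_cells = 2,
                                cell_radius = 18, rim_width = 8, seed = 6))
  path <- withr::local_tempfile(fileext = ".tiff")
  write_fov_tiff(fov, path)
  back <- read_fov_tiff(path)
  expect_equal(names(back$channels), names(fov$channels))
  expect_equal(back$channels$cy5, fov$channels$cy5, tolerance = 1e-6)
  expect_equal(back$meta$condition, fov$meta$condition)
  m1 <- measure_fov(fov); m2 <- measure_fov(back)
  expect_equal(m1$cy5_per_cell, m2$cy5_per_cell, tolerance = 1e-5)
})
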