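# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Brute-force Benjamini-Hochberg: q_i = min over j with p_(j) >= p_(i) of
# m * p_(j) / j, computed directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    candidates <- vapply(rank_i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[i] <- min(1, min(candidates))
  }
  q
}

# Chebyshev distance to background by Bellman relaxation over the eight
# neighbor shifts (pixels outside the image count as background) -
# independent of morphological erosion.
chebyshev_dt <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- nr + nc
  # pad with a background ring so the outside is distance 0
  d <- matrix(0, nr + 2, nc + 2)
  d[seq_len(nr) + 1, seq_len(nc) + 1] <- ifelse(mask > 0, big, 0)
  shift <- function(m, dr, dc) {
    out <- matrix(big, nrow(m), ncol(m))
    rs <- seq_len(nrow(m) - abs(dr)); cs <- seq_len(ncol(m) - abs(dc))
    out[rs + max(dr, 0), cs + max(dc, 0)] <- m[rs + max(-dr, 0), cs + max(-dc, 0)]
    out
  }
  repeat {
    nb <- d
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pmin(nb, shift(d, dr, dc) + 1)
    }
    nb[d == 0] <- 0
    if (identical(nb, d)) break
    d <- nb
  }
  d[seq_len(nr) + 1, seq_len(nc) + 1]
}

# Random blob mask: union of random disks on a grid, possibly touching the
# border.
random_blob_mask <- function(size = 48, n_disks = 4) {
  m <- matrix(FALSE, size, size)
  for (k in seq_len(n_disks)) {
    r <- runif(1, 3, size / 3)
    cy <- runif(1, 1, size); cx <- runif(1, 1, size)
    d2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+")
    m <- m | (d2 <= r^2)
  }
  m
}

# One-sided Fisher / hypergeometric tail by explicit enumeration of the
# probability mass function.
fisher_tail_oracle <- function(a, term_size, query_size, background_size) {
  amax <- min(term_size, query_size)
  if (a > amax) return(0)
  sum(vapply(a:amax, function(x)
    stats::dhyper(x, term_size, background_size - term_size, query_size),
    numeric(1)))
}

# Otsu threshold by brute-force sweep maximizing between-class variance
# over the 256-level histogram of the channel's range.
otsu_oracle <- function(channel) {
  rng <- range(channel)
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- hist(channel, breaks = breaks, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  total <- sum(counts)
  best_t <- breaks[2]; best_var <- -Inf
  for (k in 1:255) {
    w0 <- sum(counts[1:k]); w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_var) { best_var <- v; best_t <- breaks[k + 1] }
  }
  best_t
}

# Tiny peptide table builder for hand-computed Hi3 examples.
peptide_rows <- function(protein, intensities, condition = "LNP",
                         replicate = "rep1", batch = "batch1") {
  tibble::tibble(
    peptide_id = sprintf("%s_p%02d", protein, seq_along(intensities)),
    protein_accession = protein,
    condition = condition, replicate_id = replicate, batch_id = batch,
    intensity = intensities)
}
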