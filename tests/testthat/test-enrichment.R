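abundance_rows <- function(protein, lnp, plasma) {
  tibble::tibble(
    protein_accession = protein,
    condition = rep(c("LNP", "PLASMA"), c(length(lnp), length(plasma))),
    replicate_id = c(sprintf("rep%d", seq_along(lnp)),
                     sprintf("rep%d", seq_along(plasma))),
    batch_id = "batch1",
    abundance_fmol = c(lnp, plasma))
}

test_that("enrichment reproduces a hand-computed Welch comparison", {
  # log2 abundances (3.9, 4.0, 4.1) vs (1.9, 2.0, 2.1): log2 FC exactly 2
  dat <- dplyr::bind_rows(
    abundance_rows("PX", 2^c(3.9, 4.0, 4.1), 2^c(1.9, 2.0, 2.1)),
    abundance_rows("PN", c(10, 11, 9), c(10, 9, 11)))
  enr <- enrichment_analysis(dat)
  px <- enr[enr$protein_accession == "PX", ]
  expect_equal(px$log2_fc, 2, tolerance = 1e-12)
  hand <- t.test(c(3.9, 4.0, 4.1), c(1.9, 2.0, 2.1), var.equal = FALSE)
  expect_equal(px$p_value, hand$p.value, tolerance = 1e-12)
  expect_equal(unname(hand$statistic), 24.49, tolerance = 0.01)
  expect_lt(px$p_value, 0.001)
})

test_that("identical abundances give zero fold change and no significance", {
  dat <- dplyr::bind_rows(
    abundance_rows("PA", c(10, 11, 9), c(10, 11, 9)),
    abundance_rows("PB", c(5, 6, 7), c(7, 6, 5)))
  enr <- enrichment_analysis(dat)
  expect_equal(enr$log2_fc[enr$protein_accession == "PA"], 0, tolerance = 1e-12)
  expect_true(all(enr$class == "not_significant"))
})

test_that("swapping condition labels negates fold changes and preserves p", {
  withr::with_seed(3, {
    dat <- dplyr::bind_rows(lapply(1:8, function(i)
      abundance_rows(sprintf("P%02d", i), runif(3, 5, 50), runif(3, 5, 50))))
  })
  fwd <- enrichment_analysis(dat)
  swapped <- dat |>
    dplyr::mutate(condition = ifelse(condition == "LNP", "PLASMA", "LNP"))
  rev <- enrichment_analysis(swapped)
  key <- dplyr::left_join(tidy(fwd), tidy(rev), by = "protein_accession")
  expect_equal(key$log2_fc.x, -key$log2_fc.y, tolerance = 1e-12)
  expect_equal(key$p_value.x, key$p_value.y, tolerance = 1e-12)
})

test_that("BH q-values match a brute-force oracle and dominate raw p", {
  withr::with_seed(11, {
    for (i in 1:10) {
      p <- runif(sample(5:40, 1))
      expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
  })
  dat <- dplyr::bind_rows(lapply(1:6, function(i)
    abundance_rows(sprintf("P%02d", i), c(10, 12, 11) * i, c(5, 6, 7))))
  enr <- enrichment_analysis(dat)
  expect_true(all(enr$q_value >= enr$p_value))
  expect_equal(enr$q_value, bh_oracle(enr$p_value), tolerance = 1e-12)
})

test_that("one-condition proteins are reported separately, zeros are floored", {
  dat <- dplyr::bind_rows(
    abundance_rows("BOTH", c(10, 11, 9), c(5, 6, 7)),
    abundance_rows("LNPONLY", c(20, 22, 21), numeric(0)),
    abundance_rows("PLASMAONLY", numeric(0), c(3, 4, 5)))
  enr <- enrichment_analysis(dat)
  expect_equal(attr(enr, "lnp_only"), "LNPONLY")
  expect_equal(attr(enr, "plasma_only"), "PLASMAONLY")
  expect_equal(enr$protein_accession, "BOTH")

  withz <- dplyr::bind_rows(abundance_rows("PZ", c(0, 10, 12), c(5, 6, 7)),
                            abundance_rows("PQ", c(8, 9, 10), c(8, 9, 10)))
  expect_message(enr2 <- enrichment_analysis(withz), "floor")
  expect_true(all(is.finite(enr2$log2_fc)))
  # the floored value is half the smallest nonzero abundance of its run
  pz_lnp_rep1 <- log2(8 / 2)
  expect_equal(enr2$log2_fc[enr2$protein_accession == "PZ"],
               mean(c(pz_lnp_rep1, log2(10), log2(12))) - mean(log2(c(5, 6, 7))),
               tolerance = 1e-12)
})

test_that("rank comparison recovers monotone, reversed and null relationships", {
  rec <- tibble::tibble(protein_accession = sprintf("P%02d", 1:10),
                        log2_fc = seq(-2, 2.5, by = 0.5))
  mono <- tibble::tibble(protein_accession = rec$protein_accession,
                         relative_abundance_pct = 2^rec$log2_fc)
  out <- rank_comparison(rec, mono)
  expect_equal(out$estimate[out$metric == "spearman"], 1)
  rev <- mono |> dplyr::mutate(relative_abundance_pct = rev(relative_abundance_pct))
  expect_equal(
    rank_comparison(rec, rev)$estimate[out$metric == "spearman"], -1)

  # independent rankings: mean Spearman near zero over repeated draws
  withr::with_seed(17, {
    sp <- replicate(200, {
      r <- tibble::tibble(protein_accession = sprintf("P%02d", 1:56),
                          log2_fc = rnorm(56))
      ra <- tibble::tibble(protein_accession = r$protein_accession,
                           relative_abundance_pct = runif(56))
      rank_comparison(r, ra)$estimate[2]
    })
  })
  expect_lt(abs(mean(sp)), 0.03)

  const <- mono |> dplyr::mutate(relative_abundance_pct = 1)
  expect_warning(nul <- rank_comparison(rec, const), "Degenerate")
  expect_true(all(is.na(nul$estimate)))
})

test_that("consistent enrichment is the across-batch intersection", {
  mk <- function(acc_enriched, acc_all) {
    structure(tibble::tibble(
      protein_accession = acc_all,
      log2_fc = ifelse(acc_all %in% acc_enriched, 2, 0),
      p_value = 0.01, q_value = 0.01,
      class = ifelse(acc_all %in% acc_enriched, "enriched", "not_significant")),
      class = c("corona_enrichment", "tbl_df", "tbl", "data.frame"))
  }
  one <- consistent_enrichment(list(mk(c("A", "B"), c("A", "B", "C"))))
  expect_setequal(attr(one, "consistent_set"), c("A", "B"))

  two <- consistent_enrichment(list(
    mk(c("A", "B", "C"), LETTERS[1:4]), mk(c("B", "C", "D"), LETTERS[1:4])))
  expect_setequal(attr(two, "consistent_set"), c("B", "C"))
  expect_equal(two$n_batches_enriched[two$protein_accession == "A"], 1L)
  expect_error(consistent_enrichment(list()), "at least one")
})

test_that("always-enriched proteins are recovered across simulated batches", {
  hits <- 0L
  n_rep <- 25
  withr::with_seed(99, for (s in seq_len(n_rep)) {
    fc <- setNames(c(rep(3, 3), rep(0, 10)), sprintf("P%02d", 1:13))
    enr_by_batch <- lapply(1:3, function(b) {
      # sporadic proteins flicker on in single batches
      fc_b <- fc
      spor <- sample(names(fc)[fc == 0], 2)
      fc_b[spor] <- 3
      sim <- sim_peptide_table(proteome_sim_config(
        true_log2fc = fc_b, peptides_per_protein = 4,
        seed = s * 100 + b))
      enrichment_analysis(hi3_quantify(sim$table), exclude = "P63284")
    })
    consistent <- attr(consistent_enrichment(enr_by_batch), "consistent_set")
    if (setequal(consistent, c("P01", "P02", "P03"))) hits <- hits + 1L
  })
  expect_gte(hits / n_rep, 0.9)
})

test_that("EASE p-values match enumeration and dominate plain Fisher", {
  # background 100, term 10, query 20, overlap 8 -> table (7,13,3,77)
  bg <- sprintf("G%03d", 1:100)
  term <- bg[1:10]
  query <- bg[c(1:8, 51:62)]  # overlap 8
  ann <- tibble::tibble(term_id = "T1", accession = term)
  res <- ease_overrepresentation(query, ann, bg)
  expect_equal(res$count, 8)
  expect_equal(res$ease_p, fisher_tail_oracle(7, 10, 20, 100), tolerance = 1e-12)
  expect_equal(res$fisher_p, fisher_tail_oracle(8, 10, 20, 100), tolerance = 1e-12)
  # cross-check against stats::fisher.test on the decremented table
  ft <- fisher.test(matrix(c(7, 13, 3, 77), 2), alternative = "greater")
  expect_equal(res$ease_p, ft$p.value, tolerance = 1e-9)
  expect_true(res$pass == (res$count >= 5 && res$ease_p <= 0.05))

  # zero overlap
  ann0 <- tibble::tibble(term_id = "T0", accession = bg[91:100])
  res0 <- ease_overrepresentation(bg[1:10], ann0, bg)
  expect_equal(res0$ease_p, 1)
  expect_false(res0$pass)

  # EASE is conservative for every overlap >= 1 on small backgrounds
  withr::with_seed(5, {
    for (i in 1:50) {
      N <- sample(10:50, 1); K <- sample(1:N, 1); nq <- sample(1:N, 1)
      bgs <- sprintf("g%02d", 1:N)
      anns <- tibble::tibble(term_id = "T", accession = bgs[1:K])
      r <- ease_overrepresentation(bgs[sample(N, nq)], anns, bgs)
      expect_gte(r$ease_p + 1e-12, r$fisher_p)
    }
  })
})

test_that("query outside background errors; stray annotations are skipped", {
  bg <- c("A", "B", "C")
  ann <- tibble::tibble(term_id = "T", accession = c("A", "Z"))
  expect_error(ease_overrepresentation(c("A", "Q"), ann, bg), "subset")
  expect_warning(res <- ease_overrepresentation("A", ann, bg), "outside")
  expect_equal(res$term_size, 1)
})
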