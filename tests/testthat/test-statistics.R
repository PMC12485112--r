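rep_table <- function(condition, bio, value) {
  tibble::tibble(condition = condition, biological_replicate = bio,
                 value = value)
}

test_that("control normalization divides by the per-replicate control mean", {
  tbl <- rep_table(c("ctrl", "ctrl", "trt", "trt"),
                   rep("b1", 4), c(2, 2, 1, 4))
  norm <- normalize_to_control(tbl, "ctrl")
  expect_equal(norm$value, c(1, 1, 0.5, 2))

  two <- dplyr::bind_rows(
    rep_table(c("ctrl", "trt"), "b1", c(2, 2)),
    rep_table(c("ctrl", "trt"), "b2", c(4, 2)))
  norm2 <- normalize_to_control(two, "ctrl")
  expect_equal(norm2$value[norm2$condition == "trt"], c(1, 0.5))

  same <- rep_table(rep(c("ctrl", "a"), each = 2), rep("b1", 4), rep(3, 4))
  expect_true(all(normalize_to_control(same, "ctrl")$value == 1))
  zero <- rep_table(c("ctrl", "trt"), "b1", c(0, 5))
  expect_error(normalize_to_control(zero, "ctrl"), "Zero control")
})

test_that("nested ANOVA with one sub-value reduces to one-way ANOVA on replicates", {
  withr::with_seed(31, {
    tbl <- tibble::tibble(
      condition = rep(c("ctrl", "a", "b"), each = 4),
      biological_replicate = rep(paste0("b", 1:4), 3),
      value = rnorm(12, rep(c(0, 1, 2), each = 4)))
  })
  fit <- nested_anova_dunnett(tbl, "ctrl")
  ref <- anova(lm(value ~ condition, data = tbl))
  expect_equal(fit$anova$statistic[1], ref$`F value`[1], tolerance = 1e-9)
  expect_equal(fit$anova$p_value[1], ref$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("Dunnett adjustment agrees with multcomp and collapses at k = 1", {
  withr::with_seed(77, {
    tbl <- tibble::tibble(
      condition = rep(c("ctrl", "a", "b", "c"), each = 5),
      biological_replicate = rep(paste0("b", 1:5), 4),
      value = rnorm(20, rep(c(0, 0.8, 0, 1.5), each = 5)))
  })
  fit <- nested_anova_dunnett(tbl, "ctrl")
  mc <- multcomp::glht(
    stats::aov(value ~ condition, data = tbl |>
                 dplyr::mutate(condition = stats::relevel(factor(condition), "ctrl"))),
    linfct = multcomp::mcp(condition = "Dunnett"))
  mc_p <- summary(mc)$test$pvalues
  ord <- match(c("a", "b", "c"), fit$comparisons$condition)
  expect_equal(fit$comparisons$adjusted_p[ord], as.numeric(mc_p),
               tolerance = 5e-3, ignore_attr = TRUE)

  # single comparison: adjusted equals unadjusted
  k1 <- nested_anova_dunnett(dplyr::filter(tbl, condition %in% c("ctrl", "a")),
                             "ctrl")
  expect_equal(k1$comparisons$adjusted_p, k1$comparisons$p_value,
               tolerance = 1e-12)
})

test_that("Dunnett p-values dominate unadjusted p and grow with family size", {
  withr::with_seed(13, {
    base <- tibble::tibble(
      condition = rep(c("ctrl", "a"), each = 4),
      biological_replicate = rep(paste0("b", 1:4), 2),
      value = rnorm(8, rep(c(0, 1), each = 4)))
    extra <- tibble::tibble(
      condition = rep(c("x", "y"), each = 4),
      biological_replicate = rep(paste0("b", 1:4), 2),
      value = rnorm(8))
  })
  small <- nested_anova_dunnett(base, "ctrl")
  big <- nested_anova_dunnett(dplyr::bind_rows(base, extra), "ctrl")
  expect_true(all(small$comparisons$adjusted_p >=
                    small$comparisons$p_value - 1e-12))
  pa_small <- small$comparisons$adjusted_p[small$comparisons$condition == "a"]
  pa_big <- big$comparisons$adjusted_p[big$comparisons$condition == "a"]
  expect_gte(pa_big, pa_small - 1e-9)
})

test_that("null nested data produce no significant Dunnett comparisons", {
  withr::with_seed(41, {
    tbl <- tibble::tibble(
      condition = rep(c("ctrl", "a", "b"), each = 6),
      biological_replicate = rep(rep(c("b1", "b2", "b3"), each = 2), 3),
      value = 10 + rnorm(18, sd = 0.01))
  })
  fit <- nested_anova_dunnett(tbl, "ctrl")
  expect_false(any(fit$comparisons$significant))
  # a condition with a single biological replicate is excluded with warning
  one <- dplyr::bind_rows(tbl, rep_table("solo", "b1", 10))
  expect_warning(fit2 <- nested_anova_dunnett(one, "ctrl"), "single")
  expect_false("solo" %in% fit2$comparisons$condition)
})

test_that("repeated-measures ANOVA matches car's Geisser-Greenhouse output", {
  withr::with_seed(19, {
    n <- 8; k <- 4
    mat <- matrix(rnorm(n * k), n, k) +
      matrix(rep(c(0, 0.5, 1, 0.2), each = n), n, k) +
      rnorm(n)  # subject effects induce correlation
  })
  tbl <- tibble::tibble(
    condition = rep(paste0("c", 1:k), each = n),
    biological_replicate = rep(paste0("s", 1:n), k),
    value = as.vector(mat))
  fit <- rm_anova_gg_dunnett(tbl, "c1")

  idata <- data.frame(condition = factor(paste0("c", 1:k)))
  mlm <- stats::lm(mat ~ 1)
  cc <- car::Anova(mlm, idata = idata, idesign = ~condition, type = "III")
  s <- summary(cc)
  expect_equal(unname(fit$epsilon), unname(s$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-6)
  expect_equal(fit$anova$p_value[1],
               unname(s$pval.adjustments[1, "Pr(>F[GG])"]), tolerance = 1e-6)
})

test_that("repeated-measures ANOVA edge cases behave", {
  # two conditions: sphericity holds trivially, epsilon = 1
  withr::with_seed(23, {
    tbl <- tibble::tibble(
      condition = rep(c("ctrl", "a"), each = 5),
      biological_replicate = rep(paste0("s", 1:5), 2),
      value = rnorm(10))
  })
  fit2 <- rm_anova_gg_dunnett(tbl, "ctrl")
  expect_equal(fit2$epsilon, 1)

  # compound-symmetric data: epsilon near 1 with many subjects
  withr::with_seed(29, {
    n <- 200; k <- 4
    subj <- rnorm(n, sd = 2)
    cs <- tibble::tibble(
      condition = rep(paste0("c", 1:k), each = n),
      biological_replicate = rep(paste0("s", 1:n), k),
      value = rep(subj, k) + rnorm(n * k))
  })
  expect_gt(rm_anova_gg_dunnett(cs, "c1")$epsilon, 0.95)

  # incomplete blocks are refused with the missing cell named
  miss <- dplyr::filter(tbl, !(condition == "a" & biological_replicate == "s2"))
  expect_error(rm_anova_gg_dunnett(miss, "ctrl"), "s2")
})

test_that("flow gating matches its construction on identical and shifted samples", {
  withr::with_seed(55, {
    ctrl <- rnorm(20000, 100, 20)
    g <- flow_gate(ctrl, ctrl)
    expect_equal(g$pct_positive, 0.5, tolerance = 0.25)
    shifted <- flow_gate(ctrl, ctrl + 200)  # +10 control sds
    expect_gt(shifted$pct_positive, 99.9)
    const <- flow_gate(ctrl, rep(7, 2000))
    expect_equal(const$mfi, 7)
  })
  expect_error(flow_gate(rnorm(10), rnorm(2000)), "1000")
  expect_error(flow_gate(rnorm(2000), rnorm(2000), gate_quantile = 1.5),
               "quantile")
})

test_that("tidy and glance methods expose comparisons and fit summaries", {
  withr::with_seed(61, {
    tbl <- tibble::tibble(
      condition = rep(c("ctrl", "a", "b"), each = 6),
      biological_replicate = rep(rep(c("b1", "b2", "b3"), each = 2), 3),
      value = rnorm(18, rep(c(0, 2, 0), each = 6)))
  })
  fit <- nested_anova_dunnett(tbl, "ctrl")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$condition, c("a", "b"))
  gl <- glance(fit)
  expect_equal(gl$df, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
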