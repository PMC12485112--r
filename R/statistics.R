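#' Normalize measurements to the no-corona control
#'
#' Divides every value by the mean control value of its own biological
#' replicate, so plate-to-plate (replicate-to-replicate) scale differences
#' cancel and the control maps to 1 per replicate. This is the standard
#' normalization for luminescence readouts compared across protein-corona
#' conditions.
#'
#' @param table Data frame with columns `condition`,
#'   `biological_replicate`, `value`.
#' @param control Name of the control condition.
#' @return Tibble of the same shape with `value` replaced by the normalized
#'   value.
#' @export
normalize_to_control <- function(table, control) {
  req <- c("condition", "biological_replicate", "value")
  if (!all(req %in% names(table)))
    abort(paste("`table` must have columns:", paste(req, collapse = ", ")))
  tbl <- tibble::as_tibble(table)
  if (!control %in% tbl$condition)
    abort(sprintf("Control condition '%s' not present.", control))
  ctrl <- tbl |>
    filter(.data$condition == control) |>
    group_by(.data$biological_replicate) |>
    summarise(ctrl_mean = mean(.data$value), .groups = "drop")
  if (any(ctrl$ctrl_mean == 0)) abort("Zero control mean in a biological replicate.")
  missing <- setdiff(unique(tbl$biological_replicate), ctrl$biological_replicate)
  if (length(missing) > 0)
    abort(paste("No control values for biological replicate(s):",
                paste(missing, collapse = ", ")))
  tbl |>
    left_join(ctrl, by = "biological_replicate") |>
    mutate(value = .data$value / .data$ctrl_mean) |>
    select(-"ctrl_mean")
}

# Two-sided Dunnett adjustment: p_i = P(max_j |T_j| >= |t_i|) under the
# multivariate t with the many-to-one correlation structure. Deterministic
# given the RNG state; computed with mvtnorm's Genz-Bretz quadrature under a
# fixed local seed.
dunnett_adjust <- function(t_stats, df, n_trt, n_ctrl) {
  k <- length(t_stats)
  if (k == 1) return(2 * pt(-abs(t_stats), df))
  lambda <- sqrt(n_trt / (n_trt + n_ctrl))  # per-comparison, vs shared control
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  vapply(abs(t_stats), function(tt) {
    with_seed(20240601L, {
      1 - mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k),
                        df = as.integer(round(df)), corr = corr,
                        algorithm = mvtnorm::GenzBretz(abseps = 2e-4,
                                                       maxpts = 10000L))[1]
    })
  }, numeric(1))
}

#' Nested one-way ANOVA with Dunnett many-to-one comparisons
#'
#' Tests a condition effect when sub-replicate values (e.g. technical
#' replicates or FOV aggregates) are nested within biological replicates.
#' The condition F statistic uses the biological-replicate stratum as its
#' error: `F = MS_condition / MS_replicate(condition)` with
#' `(k - 1, N_rep - k)` degrees of freedom, so pseudo-replication at the
#' technical level cannot inflate significance. Dunnett comparisons of each
#' treatment against the control use biological-replicate means as the
#' error unit (for balanced designs this is the identical stratum), with
#' family-wise adjusted p-values from the Dunnett multivariate-t
#' distribution.
#'
#' @param table Data frame with columns `condition`,
#'   `biological_replicate`, `value` (multiple rows per biological
#'   replicate are the nested sub-replicates).
#' @param control Name of the control condition.
#' @param alpha Significance level for the `significant` flag.
#' @return Object of class `corona_nested_anova`: list with
#'   * `anova` — tibble of the nested decomposition (`term`, `df`,
#'     `sum_sq`, `mean_sq`, `statistic`, `p_value`);
#'   * `comparisons` — tibble (`condition`, `estimate`, `se`, `df`,
#'     `statistic`, `p_value`, `adjusted_p`, `significant`).
#' @export
nested_anova_dunnett <- function(table, control, alpha = 0.05) {
  req <- c("condition", "biological_replicate", "value")
  if (!all(req %in% names(table)))
    abort(paste("`table` must have columns:", paste(req, collapse = ", ")))
  tbl <- tibble::as_tibble(table) |>
    mutate(condition = as.character(.data$condition))
  if (!control %in% tbl$condition)
    abort(sprintf("Control condition '%s' not present.", control))

  # exclude conditions with a single biological replicate
  reps <- tbl |> distinct(.data$condition, .data$biological_replicate) |>
    count(.data$condition)
  singletons <- reps$condition[reps$n < 2]
  if (length(singletons) > 0) {
    warn(paste("Excluding condition(s) with a single biological replicate:",
               paste(singletons, collapse = ", ")))
    tbl <- filter(tbl, !.data$condition %in% singletons)
  }
  if (!control %in% tbl$condition)
    abort("Control condition excluded (needs >= 2 biological replicates).")

  k <- dplyr::n_distinct(tbl$condition)
  grand <- mean(tbl$value)
  rep_means <- tbl |>
    group_by(.data$condition, .data$biological_replicate) |>
    summarise(rep_mean = mean(.data$value), m = dplyr::n(), .groups = "drop")
  cond_means <- rep_means |>
    group_by(.data$condition) |>
    summarise(cond_mean = mean(.data$rep_mean), b = dplyr::n(),
              .groups = "drop")

  # two-level decomposition (balanced case; unbalanced designs fall back to
  # the replicate-means analysis below, which is what the comparisons use)
  m_bar <- mean(rep_means$m)
  ss_cond <- sum(cond_means$b * m_bar * (cond_means$cond_mean - grand)^2)
  rep_aug <- left_join(rep_means, cond_means, by = "condition")
  ss_rep <- sum(rep_aug$m * (rep_aug$rep_mean - rep_aug$cond_mean)^2)
  within <- tbl |>
    left_join(rep_means, by = c("condition", "biological_replicate")) |>
    mutate(dev2 = (.data$value - .data$rep_mean)^2)
  ss_err <- sum(within$dev2)
  df_cond <- k - 1
  df_rep <- nrow(rep_means) - k
  df_err <- nrow(tbl) - nrow(rep_means)
  ms_cond <- ss_cond / df_cond
  ms_rep <- ss_rep / df_rep
  f_cond <- ms_cond / ms_rep
  p_cond <- pf(f_cond, df_cond, df_rep, lower.tail = FALSE)

  anova_tbl <- tibble::tibble(
    term = c("condition", "biological_replicate(condition)", "within"),
    df = c(df_cond, df_rep, df_err),
    sum_sq = c(ss_cond, ss_rep, ss_err),
    mean_sq = c(ms_cond, ms_rep, ifelse(df_err > 0, ss_err / df_err, NA_real_)),
    statistic = c(f_cond, NA_real_, NA_real_),
    p_value = c(p_cond, NA_real_, NA_real_))

  # Dunnett on biological-replicate means (error unit: replicate means)
  trt <- setdiff(cond_means$condition, control)
  s2 <- rep_aug |>
    group_by(.data$condition) |>
    summarise(ss = sum((.data$rep_mean - .data$cond_mean)^2), .groups = "drop")
  df_d <- df_rep
  s2_pooled <- sum(s2$ss) / df_d
  b_of <- setNames(cond_means$b, cond_means$condition)
  mean_of <- setNames(cond_means$cond_mean, cond_means$condition)
  est <- mean_of[trt] - mean_of[control]
  se <- sqrt(s2_pooled * (1 / b_of[trt] + 1 / b_of[control]))
  t_stats <- est / se
  adj <- dunnett_adjust(t_stats, df_d, n_trt = b_of[trt],
                        n_ctrl = b_of[control])
  comparisons <- tibble::tibble(
    condition = trt,
    estimate = unname(est), se = unname(se), df = df_d,
    statistic = unname(t_stats),
    p_value = unname(2 * pt(-abs(t_stats), df_d)),
    adjusted_p = pmin(unname(adj), 1)) |>
    mutate(adjusted_p = pmax(.data$adjusted_p, .data$p_value),
           significant = .data$adjusted_p < alpha)

  structure(list(anova = anova_tbl, comparisons = comparisons,
                 control = control, alpha = alpha),
            class = "corona_nested_anova")
}

#' Repeated-measures one-way ANOVA with Geisser-Greenhouse correction and
#' Dunnett comparisons
#'
#' For complete-block designs where every condition is measured in every
#' biological replicate (e.g. normalized luminescence per plate). The
#' within-subjects F uses the condition x subject interaction as error;
#' both degrees of freedom are multiplied by the Greenhouse-Geisser epsilon
#' computed from the sample covariance matrix of the subject x condition
#' measurements, guarding against sphericity violations. Dunnett
#' comparisons of each condition against the control use the
#' within-subject error mean square and its uncorrected degrees of freedom.
#'
#' @param table Data frame with columns `condition`,
#'   `biological_replicate`, `value`; one value per condition x replicate
#'   (technical replicates should be averaged first).
#' @param control Name of the control condition.
#' @param alpha Significance level for the `significant` flag.
#' @return Object of class `corona_rm_anova`: list with `anova`
#'   (within-subjects table including `epsilon` and GG-corrected p) and
#'   `comparisons` (as in [nested_anova_dunnett()]).
#' @export
rm_anova_gg_dunnett <- function(table, control, alpha = 0.05) {
  req <- c("condition", "biological_replicate", "value")
  if (!all(req %in% names(table)))
    abort(paste("`table` must have columns:", paste(req, collapse = ", ")))
  tbl <- tibble::as_tibble(table) |>
    mutate(condition = as.character(.data$condition)) |>
    group_by(.data$condition, .data$biological_replicate) |>
    summarise(value = mean(.data$value), .groups = "drop")
  if (!control %in% tbl$condition)
    abort(sprintf("Control condition '%s' not present.", control))

  wide <- tbl |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    arrange(.data$biological_replicate)
  conds <- setdiff(names(wide), "biological_replicate")
  mat <- as.matrix(wide[, conds])
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    abort(paste0("Incomplete blocks; missing cells: ",
                 paste(sprintf("%s x %s", wide$biological_replicate[miss[, 1]],
                               conds[miss[, 2]]), collapse = ", ")))
  }
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2) abort("Need >= 2 biological replicates.")

  subj_means <- rowMeans(mat); cond_means <- colMeans(mat)
  grand <- mean(mat)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_cond <- k - 1; df_err <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df_cond; ms_err <- ss_err / df_err
  f_stat <- ms_cond / ms_err

  # Greenhouse-Geisser epsilon from the sample covariance of conditions
  S <- stats::cov(mat)
  mean_diag <- mean(diag(S)); mean_all <- mean(S)
  row_means <- rowMeans(S)
  num <- (k * (mean_diag - mean_all))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * mean_all^2)
  epsilon <- if (k == 2) 1 else min(1, max(num / den, 1 / (k - 1)))
  p_gg <- pf(f_stat, epsilon * df_cond, epsilon * df_err, lower.tail = FALSE)

  anova_tbl <- tibble::tibble(
    term = c("condition", "subject", "error"),
    df = c(df_cond, n - 1, df_err),
    sum_sq = c(ss_cond, ss_subj, ss_err),
    mean_sq = c(ms_cond, ss_subj / (n - 1), ms_err),
    statistic = c(f_stat, NA_real_, NA_real_),
    epsilon = c(epsilon, NA_real_, NA_real_),
    p_value = c(p_gg, NA_real_, NA_real_))

  trt <- setdiff(conds, control)
  est <- cond_means[trt] - cond_means[control]
  se <- sqrt(ms_err * 2 / n)
  t_stats <- est / se
  adj <- dunnett_adjust(t_stats, df_err, n_trt = rep(n, length(trt)),
                        n_ctrl = n)
  comparisons <- tibble::tibble(
    condition = trt,
    estimate = unname(est), se = se, df = df_err,
    statistic = unname(t_stats),
    p_value = unname(2 * pt(-abs(t_stats), df_err)),
    adjusted_p = pmin(unname(adj), 1)) |>
    mutate(adjusted_p = pmax(.data$adjusted_p, .data$p_value),
           significant = .data$adjusted_p < alpha)

  structure(list(anova = anova_tbl, comparisons = comparisons,
                 control = control, alpha = alpha, epsilon = epsilon),
            class = "corona_rm_anova")
}

#' Flow-cytometry positive gate and summary statistics
#'
#' Sets the positive gate at a high quantile of the untreated-control event
#' intensities, then reports the percentage of sample events above the gate
#' and the sample's mean fluorescence intensity (MFI), both over all events
#' and over gated (positive) events.
#'
#' @param control_events,sample_events Numeric vectors of per-event
#'   intensities (>= 1000 events each).
#' @param gate_quantile Control quantile defining the gate (default 0.995,
#'   i.e. 0.5% false-positive rate on the control by construction).
#' @return One-row tibble: `gate_threshold`, `pct_positive`, `mfi`,
#'   `mfi_gated`, `n_events`.
#' @export
flow_gate <- function(control_events, sample_events, gate_quantile = 0.995) {
  if (length(control_events) < 1000 || length(sample_events) < 1000)
    abort("Need >= 1000 events per sample.")
  if (gate_quantile <= 0 || gate_quantile >= 1)
    abort("`gate_quantile` must be in (0, 1).")
  gate <- unname(quantile(control_events, gate_quantile, type = 7))
  pos <- sample_events > gate
  tibble::tibble(
    gate_threshold = gate,
    pct_positive = 100 * mean(pos),
    mfi = mean(sample_events),
    mfi_gated = if (any(pos)) mean(sample_events[pos]) else NA_real_,
    n_events = length(sample_events))
}

#' @export
print.corona_nested_anova <- function(x, ...) {
  cat("<corona_nested_anova> control =", x$control, "\n")
  print(x$anova); cat("Dunnett comparisons:\n"); print(x$comparisons)
  invisible(x)
}

#' @export
print.corona_rm_anova <- function(x, ...) {
  cat("<corona_rm_anova> control =", x$control,
      " GG epsilon =", round(x$epsilon, 3), "\n")
  print(x$anova); cat("Dunnett comparisons:\n"); print(x$comparisons)
  invisible(x)
}
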