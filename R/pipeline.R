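#' Default pipeline configuration
#'
#' Returns the full default configuration for [run_pipeline()]: simulation
#' settings for every input type, analysis thresholds (window width,
#' gradient R-squared minimum, q threshold, erosion depth, gate quantile)
#' and the imaging condition layout. Any subset can be overridden by the
#' `config` argument of [run_pipeline()]; every threshold used is echoed in
#' the run report.
#'
#' @param seed Master seed; per-stage sub-streams are derived from it.
#' @return Nested list of settings.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    fractions = list(window_width = 5, r2_min = 0.98, sim = list()),
    proteomics = list(q_threshold = 0.05, sim = list(n_batches = 2L)),
    imaging = list(
      erosion_n = 10, n_fov_per_tech = 3, n_bio = 2, n_tech = 2,
      sim = list(image_shape = c(128L, 128L), n_cells = 4,
                 cell_radius = 20, rim_width = 10),
      conditions = list(no_corona = list(puncta_per_cell_inner = 3),
                        corona = list(puncta_per_cell_inner = 15))),
    flow = list(gate_quantile = 0.995,
                sim = list(n_events = 5000, treated_shift = 60)))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the synthetic corona-quantification pipeline end to end
#'
#' Orchestrates `simulate -> fractions -> proteomics -> imaging -> stats`
#' from a single configuration, persisting every intermediate as CSV / TIFF
#' / JSON under `out_dir` and returning (and writing) a machine-readable
#' run report. Identical configuration and seed produce an identical
#' report; each analysis stage reads only the persisted artifacts of the
#' simulate stage, so stages can be re-run independently.
#'
#' @param config `NULL` for defaults, a nested list of overrides, or a path
#'   to a YAML file with the same structure as
#'   [default_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, in order, from
#'   `simulate`, `fractions`, `proteomics`, `imaging`, `stats`.
#' @return The run report (nested list of class `corona_report`),
#'   invisibly; also written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("corona_run_"),
                         stages = c("simulate", "fractions", "proteomics",
                                    "imaging", "stats")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_pipeline_config(), config %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed

  report <- list(
    package = "coronaquant",
    version = as.character(utils::packageVersion("coronaquant")),
    seed = seed, config = cfg, stages_run = stages)

  if ("simulate" %in% stages) {
    fr_cfg <- do.call(fraction_sim_config,
                      c(cfg$fractions$sim, list(seed = derive_seed(seed, "fr"))))
    fr <- sim_fraction_profile(fr_cfg)
    readr::write_csv(fr$profile, file.path(out_dir, "fraction_profile.csv"))
    jsonlite::write_json(
      list(peak_mass = fr$truth$peak_mass,
           late_peak_mass = fr$truth$late_peak_mass,
           true_pct_2_6 = true_window_pct(fr, 2, 6)),
      file.path(out_dir, "fraction_truth.json"), digits = NA)

    pr_cfg <- do.call(proteome_sim_config,
                      c(cfg$proteomics$sim, list(seed = derive_seed(seed, "pr"))))
    pr <- sim_peptide_table(pr_cfg)
    readr::write_csv(pr$table, file.path(out_dir, "peptide_table.csv"))
    jsonlite::write_json(
      list(true_log2fc = as.list(pr$truth$true_log2fc),
           enriched = pr$truth$enriched, depleted = pr$truth$depleted,
           standard_accession = pr_cfg$standard_accession,
           spike_fmol = pr_cfg$spike_fmol),
      file.path(out_dir, "proteome_truth.json"), auto_unbox = TRUE, digits = NA)

    fov_truth <- list()
    fov_idx <- 0L
    for (cond in names(cfg$imaging$conditions)) {
      for (b in seq_len(cfg$imaging$n_bio)) {
        for (t in seq_len(cfg$imaging$n_tech)) {
          for (f in seq_len(cfg$imaging$n_fov_per_tech)) {
            fov_idx <- fov_idx + 1L
            fcfg <- do.call(fov_sim_config, c(
              .merge_config(cfg$imaging$sim, cfg$imaging$conditions[[cond]]),
              list(seed = derive_seed(seed, paste("fov", cond, b, t, f)))))
            fov <- sim_fov(fcfg, condition = cond,
                           biological_replicate = sprintf("bio%d", b),
                           technical_replicate = sprintf("tech%d", t),
                           fov_index = fov_idx)
            write_fov_tiff(fov, file.path(out_dir,
                                          sprintf("fov_%03d.tiff", fov_idx)))
            fov_truth[[length(fov_truth) + 1L]] <- list(
              fov_index = fov_idx, condition = cond,
              n_cells = fov$truth$n_cells,
              counts = as.list(fov$truth$counts),
              per_cell_signal = fov$truth$per_cell_signal,
              outer_fraction = fov$truth$outer_fraction)
          }
        }
      }
    }
    jsonlite::write_json(fov_truth, file.path(out_dir, "fov_truth.json"),
                         auto_unbox = TRUE, digits = NA)

    fl <- do.call(sim_flow_sample,
                  c(cfg$flow$sim, list(gate_quantile = cfg$flow$gate_quantile,
                                       seed = derive_seed(seed, "flow"))))
    readr::write_csv(fl$events, file.path(out_dir, "flow_events.csv"))
    jsonlite::write_json(fl$truth, file.path(out_dir, "flow_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    report$simulate <- list(
      artifacts = list(fractions = "fraction_profile.csv",
                       proteome = "peptide_table.csv",
                       fov = sprintf("fov_%%03d.tiff (n = %d)", fov_idx),
                       flow = "flow_events.csv"))
  }

  if ("fractions" %in% stages) {
    profile <- read_fraction_profile(file.path(out_dir, "fraction_profile.csv"))
    qc <- check_gradient_linearity(profile, r2_min = cfg$fractions$r2_min)
    win <- select_fractions(profile, k = cfg$fractions$window_width)
    readr::write_csv(bind_rows(qc), file.path(out_dir, "gradient_qc.csv"))
    jsonlite::write_json(as.list(win), file.path(out_dir, "selected_window.json"),
                         auto_unbox = TRUE, digits = NA)
    report$fractions <- list(qc_pass = qc$pass, r_squared = qc$r_squared,
                             window = list(start = win$start, end = win$end,
                                           recovery_pct = win$recovery_pct))
  }

  if ("proteomics" %in% stages) {
    peptides <- read_peptide_table(file.path(out_dir, "peptide_table.csv"))
    truth <- jsonlite::read_json(file.path(out_dir, "proteome_truth.json"),
                                 simplifyVector = TRUE)
    abund <- hi3_quantify(peptides, standard_accession = truth$standard_accession,
                          spike_fmol = truth$spike_fmol)
    readr::write_csv(abund, file.path(out_dir, "protein_abundance.csv"))
    cv <- peptide_cv_summary(peptides)
    readr::write_csv(cv$peptides, file.path(out_dir, "peptide_cv.csv"))
    batches <- split(abund, abund$batch_id)
    enr_by_batch <- lapply(batches, enrichment_analysis,
                           q_threshold = cfg$proteomics$q_threshold,
                           exclude = truth$standard_accession)
    enr_all <- enrichment_analysis(abund,
                                   q_threshold = cfg$proteomics$q_threshold,
                                   exclude = truth$standard_accession)
    readr::write_csv(tidy(enr_all), file.path(out_dir, "enrichment.csv"))
    consistent <- consistent_enrichment(enr_by_batch)
    readr::write_csv(tibble::as_tibble(consistent),
                     file.path(out_dir, "consistent_enrichment.csv"))
    g <- glance(enr_all)
    report$proteomics <- list(
      median_cv_pct = setNames(as.list(cv$medians$median_cv_pct),
                               cv$medians$condition),
      n_tested = g$n_tested, n_enriched = g$n_enriched,
      n_depleted = g$n_depleted,
      consistent_set = attr(consistent, "consistent_set"))
  }

  if ("imaging" %in% stages) {
    tiffs <- sort(list.files(out_dir, pattern = "^fov_\\d+\\.tiff$",
                             full.names = TRUE))
    measurements <- bind_rows(lapply(tiffs, function(p)
      measure_fov(read_fov_tiff(p), erosion_n = cfg$imaging$erosion_n)))
    readr::write_csv(measurements, file.path(out_dir, "fov_measurements.csv"))
    reps <- aggregate_replicates(measurements)
    readr::write_csv(reps$technical, file.path(out_dir, "replicates_technical.csv"))
    readr::write_csv(reps$biological, file.path(out_dir, "replicates_biological.csv"))
    per_cond <- reps$biological |>
      group_by(.data$condition) |>
      summarise(mean_cy5_per_cell = mean(.data$cy5_per_cell),
                mean_outer_fraction = mean(.data$outer_fraction),
                .groups = "drop")
    report$imaging <- list(per_condition = purrr::transpose(as.list(per_cond)) |>
                             setNames(per_cond$condition))
  }

  if ("stats" %in% stages) {
    tech <- readr::read_csv(file.path(out_dir, "replicates_technical.csv"),
                            show_col_types = FALSE)
    ctrl <- names(cfg$imaging$conditions)[1]
    nested <- nested_anova_dunnett(
      tech |> mutate(value = .data$cy5_per_cell), control = ctrl)
    readr::write_csv(tidy(nested), file.path(out_dir, "nested_dunnett.csv"))
    events <- readr::read_csv(file.path(out_dir, "flow_events.csv"),
                              show_col_types = FALSE)
    gate <- flow_gate(events$intensity[events$group == "control"],
                      events$intensity[events$group == "treated"],
                      gate_quantile = cfg$flow$gate_quantile)
    readr::write_csv(gate, file.path(out_dir, "flow_gate.csv"))
    report$stats <- list(
      nested_anova = as.list(glance(nested)),
      dunnett = purrr::transpose(as.list(tidy(nested))) |>
        setNames(tidy(nested)$condition),
      flow = as.list(gate))
  }

  class(report) <- "corona_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' @export
print.corona_report <- function(x, ...) {
  cat("<corona_report> seed", x$seed, "- stages:",
      paste(x$stages_run, collapse = ", "), "\n")
  if (!is.null(x$fractions))
    cat(sprintf("  fractions: window %d-%d, recovery %.1f%%, QC pass %s\n",
                x$fractions$window$start, x$fractions$window$end,
                x$fractions$window$recovery_pct, x$fractions$qc_pass))
  if (!is.null(x$proteomics))
    cat(sprintf("  proteomics: %d tested, %d enriched, %d depleted\n",
                x$proteomics$n_tested, x$proteomics$n_enriched,
                x$proteomics$n_depleted))
  invisible(x)
}
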