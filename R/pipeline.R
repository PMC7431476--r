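# End-to-end orchestration: generate (or load) -> score -> analyse ->
# simulate -> report, with explicit seeds and machine-readable outputs.

#' Pipeline configuration
#'
#' Bundles the input (a [cohort_spec()] to generate from, or an existing
#' experiment / response table plus geometry), the analysis switches and the
#' output directory.  Every switch and seed is serialised into the run
#' manifest so a run can be reproduced exactly.
#'
#' @param spec A [cohort_spec()] used to generate synthetic data (ignored
#'   when `experiment` is given).
#' @param experiment An existing `synthetic_experiment`, or `NULL`.
#' @param iterations Monte Carlo iterations for the sketch simulation.
#' @param simulation_seed Seed for the simulation stage.
#' @param sign_convention Direction-error sign convention for the
#'   simulation; see [error_model()].
#' @param sphericity_correction Apply Greenhouse-Geisser correction in the
#'   mixed ANOVAs.
#' @param trend_error Error term for trend contrasts; see
#'   [trend_contrasts()].
#' @param outdir Output directory for CSV/JSON artefacts, or `NULL` to skip
#'   writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), experiment = NULL,
                            iterations = 1000, simulation_seed = 1L,
                            sign_convention = c("symmetric", "positive"),
                            sphericity_correction = FALSE,
                            trend_error = c("contrast_specific", "pooled"),
                            outdir = NULL) {
  structure(list(spec = spec, experiment = experiment,
                 iterations = iterations,
                 simulation_seed = as.integer(simulation_seed),
                 sign_convention = match.arg(sign_convention),
                 sphericity_correction = sphericity_correction,
                 trend_error = match.arg(trend_error),
                 outdir = outdir),
            class = "pipeline_config")
}

# analysed measures: score column, whether analysed on the Fisher-z scale
pipeline_measures <- function() {
  data.frame(
    measure = c("direction_error", "route_distance_correlation",
                "straight_distance_correlation", "route_ratio",
                "straight_ratio", "sketch_bidim_r"),
    column = c("mean_abs_direction_error", "route_distance_correlation",
               "straight_distance_correlation", "mean_route_ratio",
               "mean_straight_ratio", "sketch_bidim_r"),
    fisher_z = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) an experiment, scores every participant-session,
#' runs the mixed ANOVA and trend contrasts for each measure on the two
#' experimental conditions, compares each condition with the average group
#' (summary-statistic t tests and Cohen's d), runs the sketch-map Monte
#' Carlo simulation for first/last sessions of each condition and the
#' average group, and writes tidy CSVs, a JSON report and a run manifest
#' when `config$outdir` is set.  Correlation measures are Fisher-z
#' transformed before analysis and back-transformed for display.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with elements `scores`,
#'   `anova`, `trends`, `group_comparisons`, `simulation`, `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  experiment <- config$experiment %||% generate_experiment(config$spec)
  spec <- experiment$spec
  message("pipeline: scoring ", nrow(experiment$responses), " response rows")
  scores <- score_experiment(experiment$responses, experiment$routes,
                             paths = experiment$paths,
                             standard_m = spec$standard_m)
  exp_scores <- scores[scores$condition != "average", ]
  avg_scores <- scores[scores$condition == "average", ]
  measures <- pipeline_measures()
  have_both_conditions <- length(unique(exp_scores$condition)) == 2L

  anova <- list()
  trends <- list()
  for (i in seq_len(nrow(measures))) {
    col <- measures$column[i]
    if (all(is.na(exp_scores[[col]]))) next
    d <- data.frame(participant_id = exp_scores$participant_id,
                    condition = exp_scores$condition,
                    session = exp_scores$session,
                    value = if (measures$fisher_z[i])
                      fisher_z(clamp_r(exp_scores[[col]])) else
                        exp_scores[[col]])
    anova[[measures$measure[i]]] <-
      mixed_anova(d, sphericity_correction = config$sphericity_correction)
    if (spec$sessions >= 4L) {
      trends[[measures$measure[i]]] <-
        trend_contrasts(d, error = config$trend_error)
    }
  }
  message("pipeline: fitted ", length(anova), " mixed ANOVA table(s)")

  group_comparisons <- NULL
  if (nrow(avg_scores) > 0L) {
    cmp <- list()
    for (i in seq_len(nrow(measures))) {
      col <- measures$column[i]
      if (all(is.na(exp_scores[[col]])) || all(is.na(avg_scores[[col]]))) next
      to_scale <- function(x) if (measures$fisher_z[i])
        fisher_z(clamp_r(x)) else x
      avg_vals <- to_scale(avg_scores[[col]][avg_scores$session == 1L])
      for (cond in unique(exp_scores$condition)) {
        per_subj <- tapply(
          to_scale(exp_scores[[col]][exp_scores$condition == cond]),
          exp_scores$participant_id[exp_scores$condition == cond], mean)
        # degenerate (noise-free) cells have zero pooled variance; report
        # t = 0 when the means agree rather than failing the whole run
        tt <- tryCatch(
          independent_t_from_summary(as.numeric(per_subj), avg_vals),
          error = function(e) {
            if (isTRUE(all.equal(mean(per_subj), mean(avg_vals)))) {
              list(t = 0, df = length(per_subj) + length(avg_vals) - 2,
                   p = 1, d = 0)
            } else {
              list(t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_)
            }
          })
        cmp[[length(cmp) + 1L]] <- data.frame(
          measure = measures$measure[i], condition = cond,
          mean_condition = mean(per_subj), mean_average = mean(avg_vals),
          t = tt$t, df = tt$df, p = tt$p, d = tt$d)
      }
    }
    group_comparisons <- do.call(rbind, cmp)
    rownames(group_comparisons) <- NULL
  }

  simulation <- NULL
  if (!all(is.na(scores$sketch_bidim_r)) &&
      !all(is.na(scores$mean_abs_direction_error))) {
    cells <- expand.grid(condition = unique(exp_scores$condition),
                         session = unique(c(1L, spec$sessions)),
                         stringsAsFactors = FALSE)
    if (nrow(avg_scores) > 0L) {
      cells <- rbind(cells, data.frame(condition = "average", session = 1L))
    }
    sim_rows <- list()
    for (i in seq_len(nrow(cells))) {
      cell <- scores[scores$condition == cells$condition[i] &
                       scores$session == cells$session[i], ]
      if (nrow(cell) < 2L || all(is.na(cell$sketch_bidim_r))) next
      model <- error_model_from_scores(
        cell, sign_convention = config$sign_convention)
      sim <- run_simulation(experiment$routes[[cells$session[i]]], model,
                            iterations = config$iterations,
                            seed = config$simulation_seed + i)
      cmp <- compare_observed_vs_simulated(cell$sketch_bidim_r, sim)
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        condition = cells$condition[i], session = cells$session[i],
        observed_r = cmp$observed_mean_r, simulated_r = cmp$simulated_mean_r,
        t = cmp$t, df = cmp$df, p = cmp$p)
    }
    simulation <- do.call(rbind, sim_rows)
    rownames(simulation) <- NULL
    message("pipeline: simulation table with ", nrow(simulation), " cell(s)")
  }

  manifest <- list(
    package = "cogmapr",
    package_version = as.character(utils::packageVersion("cogmapr")),
    r_version = as.character(getRversion()),
    spec_seed = spec$seed,
    simulation_seed = config$simulation_seed,
    iterations = config$iterations,
    sign_convention = config$sign_convention,
    sphericity_correction = config$sphericity_correction,
    trend_error = config$trend_error,
    n_participants = length(unique(scores$participant_id)),
    sessions = spec$sessions)

  report <- structure(list(scores = scores, anova = anova, trends = trends,
                           group_comparisons = group_comparisons,
                           simulation = simulation, manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Write a pipeline report to disk
#'
#' Tidy CSVs (scores, ANOVA tables, trends, comparisons, simulation) plus
#' `report.json` and `manifest.json`.  No binary formats.
#'
#' @param report A `pipeline_report`.
#' @param outdir Output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$scores, file.path(outdir, "session_scores.csv"),
                   row.names = FALSE)
  bind_tables <- function(lst) {
    do.call(rbind, lapply(names(lst), function(nm) {
      cbind(data.frame(measure = nm), as.data.frame(lst[[nm]]))
    }))
  }
  if (length(report$anova) > 0L) {
    utils::write.csv(bind_tables(report$anova),
                     file.path(outdir, "anova_tables.csv"), row.names = FALSE)
  }
  if (length(report$trends) > 0L) {
    utils::write.csv(bind_tables(report$trends),
                     file.path(outdir, "trend_contrasts.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$group_comparisons)) {
    utils::write.csv(report$group_comparisons,
                     file.path(outdir, "group_comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$simulation)) {
    utils::write.csv(report$simulation,
                     file.path(outdir, "simulation_vs_observed.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(manifest = report$manifest,
         anova = lapply(report$anova, as.data.frame),
         trends = lapply(report$trends, as.data.frame),
         group_comparisons = report$group_comparisons,
         simulation = report$simulation),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  scores: %d participant-sessions\n", nrow(x$scores)))
  cat(sprintf("  ANOVA tables: %s\n", paste(names(x$anova), collapse = ", ")))
  if (!is.null(x$simulation)) {
    cat("  simulation vs observed:\n")
    print(x$simulation, digits = 3)
  }
  invisible(x)
}
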