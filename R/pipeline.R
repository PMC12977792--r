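#' Pipeline configuration
#'
#' Stage toggles and parameters for the end-to-end run: simulate (or
#' load) a cohort, compute the index grid, match, fit trajectory models,
#' and run the discrimination/regression suite. Every output directory
#' carries the seed and the configuration for provenance; deterministic
#' stages rerun byte-identically under the same configuration.
#'
#' @param sim a [sim_config()] for the simulate stage (ignored when
#'   `measurements_path`/`covariates_path` point at an existing cohort)
#' @param measurements_path,covariates_path optional CSV paths of a
#'   pre-existing cohort (skips simulation)
#' @param match run the matching stage (default `TRUE`)
#' @param trajectories run the trajectory-model stage (default `TRUE`)
#' @param predict run the model-suite stage (default `TRUE`)
#' @param trajectory_marker marker for the trajectory model
#' @param trajectory_interval bin width in hours for the trajectory model
#' @param n_days trajectory span in ICU days
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(sim = sim_config(),
                            measurements_path = NULL,
                            covariates_path = NULL,
                            match = TRUE, trajectories = TRUE,
                            predict = TRUE,
                            trajectory_marker = "lactate",
                            trajectory_interval = 24, n_days = 10) {
  structure(list(sim = sim, measurements_path = measurements_path,
                 covariates_path = covariates_path, match = match,
                 trajectories = trajectories, predict = predict,
                 trajectory_marker = trajectory_marker,
                 trajectory_interval = trajectory_interval,
                 n_days = n_days),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  # order-stable FNV-1a over the serialized configuration
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in dependency order, handing flat CSV/JSON files
#' between them so each stage is independently inspectable: cohort
#' tables, ground truth (for simulated cohorts), index grid, matched
#' sets and balance, trajectory EMMs/contrasts, and the analysis report.
#' Warnings raised by stages (TUDR fallback, unmatched cases) are
#' collected into `warnings.txt` and surfaced in the rendered report.
#'
#' @param config a [pipeline_config()]
#' @param out_dir run directory (created; existing files overwritten)
#' @return invisibly, the run directory path; side effect: stage outputs
#'   written under `out_dir`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  warnings_log <- character(0)
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = log_warning),
             error = function(e) {
               stop_icumet("stage", "stage '", name, "' failed: ",
                           conditionMessage(e))
             })
  }

  jsonlite::write_json(
    list(fingerprint = config_fingerprint(config),
         seed = config$sim$seed,
         package_version = as.character(utils::packageVersion("icumet")),
         config = config),
    file.path(out_dir, "run_config.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)

  # -- simulate / load ------------------------------------------------
  if (!is.null(config$measurements_path)) {
    cohort <- stage("load", read_cohort(config$measurements_path,
                                        config$covariates_path))
  } else {
    sim <- stage("simulate", simulate_cohort(config$sim))
    cohort <- sim$cohort
    write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
              row.names = FALSE)
  }
  write_cohort(cohort, out_dir)

  # -- indices --------------------------------------------------------
  idx <- stage("indices", cohort_index_table(cohort))
  write.csv(idx, file.path(out_dir, "indices.csv"), row.names = FALSE)

  # -- match ----------------------------------------------------------
  matched <- NULL
  if (config$match) {
    matched <- stage("match", match_cases(cohort))
    write.csv(matched$sets, file.path(out_dir, "matched_sets.csv"),
              row.names = FALSE)
    write.csv(matched$balance, file.path(out_dir, "balance.csv"),
              row.names = FALSE)
    if (nrow(matched$unmatched) > 0L) {
      warnings_log <- c(warnings_log,
                        paste(nrow(matched$unmatched),
                              "case(s) unmatched (no control in caliper)"))
      write.csv(matched$unmatched, file.path(out_dir, "unmatched.csv"),
                row.names = FALSE)
    }
  }

  # -- trajectories ---------------------------------------------------
  if (config$trajectories) {
    tw <- stage("trajectories", {
      tab <- interval_twa_table(cohort, marker = config$trajectory_marker,
                                interval_hours = config$trajectory_interval,
                                n_days = config$n_days)
      fit <- fit_trajectory_model(tab,
                                  interval_hours = config$trajectory_interval)
      emm <- emm_daily_contrasts(fit, days = seq_len(config$n_days))
      list(fit = fit, emm = emm)
    })
    write.csv(tw$emm$emm, file.path(out_dir, "trajectory_emm.csv"),
              row.names = FALSE)
    write.csv(tw$emm$contrasts, file.path(out_dir,
                                          "trajectory_contrasts.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(marker = config$trajectory_marker,
           interval_hours = config$trajectory_interval,
           sigma_intercept = tw$fit$sigma_intercept,
           ar1_rho = tw$fit$ar1_rho, sigma_resid = tw$fit$sigma_resid,
           logLik = tw$fit$logLik, AIC = tw$fit$AIC,
           group_test = tw$fit$group_test,
           interaction_test = tw$fit$interaction_test),
      file.path(out_dir, "trajectory_fit.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # -- predict --------------------------------------------------------
  if (config$predict) {
    report <- stage("predict",
                    run_model_suite(idx, matched = matched,
                                    covariate_data = cohort$covariates))
    warnings_log <- c(warnings_log, report$notes)
    if (!is.null(report$univariable)) {
      write.csv(report$univariable, file.path(out_dir, "univariable.csv"),
                row.names = FALSE)
    }
    if (!is.null(report$roc)) {
      write.csv(report$roc, file.path(out_dir, "roc.csv"),
                row.names = FALSE)
    }
    multi_json <- lapply(report$multivariable, function(f) {
      if (is.null(f)) NULL else list(variance = f$variance, n = f$n,
                                     coef = f$coef, vif = f$vif)
    })
    jsonlite::write_json(
      list(multivariable = multi_json,
           significant_indices = report$significant_indices,
           delong = report$delong, notes = report$notes),
      file.path(out_dir, "model_suite.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  }

  writeLines(warnings_log, file.path(out_dir, "warnings.txt"))
  invisible(out_dir)
}

read_if <- function(path) {
  if (file.exists(path)) read.csv(path, stringsAsFactors = FALSE) else NULL
}

#' Render a human-readable report for a pipeline run
#'
#' Assembles the stage outputs of [run_pipeline()] into a markdown report
#' (index comparison, balance, trajectory contrasts, AUC and regression
#' sections). Missing stage outputs are marked absent rather than
#' failing, so partial runs still render.
#'
#' @param run_dir directory produced by [run_pipeline()]
#' @param file output file (default `report.md` inside `run_dir`)
#' @return invisibly, the markdown text (character vector of lines)
#' @export
render_report <- function(run_dir, file = file.path(run_dir, "report.md")) {
  if (!dir.exists(run_dir)) stop_icumet("io", "no such run directory: ",
                                        run_dir)
  lines <- c("# icumet pipeline report", "")
  cfgp <- file.path(run_dir, "run_config.json")
  if (file.exists(cfgp)) {
    cfg <- jsonlite::read_json(cfgp)
    lines <- c(lines,
               sprintf("Run fingerprint `%s`, seed %s, icumet %s.",
                       cfg$fingerprint, cfg$seed, cfg$package_version), "")
  }
  covs <- read_if(file.path(run_dir, "covariates.csv"))
  if (!is.null(covs)) {
    lines <- c(lines, "## Cohort", "",
               sprintf("%d patients, %d non-survivors (%.1f%%).",
                       nrow(covs), sum(covs$outcome),
                       100 * mean(covs$outcome)), "")
  }
  bal <- read_if(file.path(run_dir, "balance.csv"))
  lines <- c(lines, "## Covariate balance", "")
  if (!is.null(bal)) {
    lines <- c(lines,
               "covariate | SMD before | SMD after | pass",
               "--- | --- | --- | ---",
               sprintf("%s | %.3f | %.3f | %s", bal$covariate,
                       bal$smd_before, bal$smd_after, bal$pass), "")
  } else {
    lines <- c(lines, "_stage output absent_", "")
  }
  uni <- read_if(file.path(run_dir, "univariable.csv"))
  lines <- c(lines, "## Univariable screen", "")
  if (!is.null(uni)) {
    lines <- c(lines,
               "index | OR | 95% CI | p",
               "--- | --- | --- | ---",
               sprintf("%s | %.3f | [%.3f, %.3f] | %.4g", uni$index,
                       uni$or, uni$or_lower, uni$or_upper, uni$p), "")
  } else {
    lines <- c(lines, "_stage output absent_", "")
  }
  roc <- read_if(file.path(run_dir, "roc.csv"))
  lines <- c(lines, "## Discrimination (AUC, DeLong 95% CI)", "")
  if (!is.null(roc)) {
    lines <- c(lines,
               "index | AUC | 95% CI | survival-directed",
               "--- | --- | --- | ---",
               sprintf("%s | %.3f | [%.3f, %.3f] | %s", roc$index, roc$auc,
                       roc$ci_lower, roc$ci_upper, roc$predicts_survival),
               "")
  } else {
    lines <- c(lines, "_stage output absent_", "")
  }
  ctr <- read_if(file.path(run_dir, "trajectory_contrasts.csv"))
  lines <- c(lines, "## Daily trajectory contrasts (Bonferroni)", "")
  if (!is.null(ctr)) {
    lines <- c(lines,
               "day | estimate | adj. p",
               "--- | --- | ---",
               sprintf("%d | %.3f | %.4g", ctr$day, ctr$estimate,
                       ctr$p_adj), "")
  } else {
    lines <- c(lines, "_stage output absent_", "")
  }
  wpath <- file.path(run_dir, "warnings.txt")
  if (file.exists(wpath)) {
    w <- readLines(wpath)
    if (length(w) > 0L) {
      lines <- c(lines, "## Warnings", "", paste("-", w), "")
    }
  }
  writeLines(lines, file)
  invisible(lines)
}
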