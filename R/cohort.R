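#' @importFrom stats AIC approx as.formula binomial coef complete.cases
#'   cor fisher.test fitted glm logLik median model.matrix pchisq plogis
#'   pnorm qlogis qnorm quantile rbinom rexp rnorm runif sd setNames var
#'   vcov wilcox.test ave
#' @importFrom utils read.csv write.csv head combn packageVersion
NULL

MEAS_COLS <- c("patient_id", "t_hours", "glucose_mgdl", "lactate_mmoll")
COV_COLS <- c("patient_id", "outcome", "icu_los_hours", "age", "sex", "bmi",
              "gcs", "isolated_tbi", "hypertension", "ckd", "saps2")

#' Construct a blood-gas cohort
#'
#' A cohort couples a long table of timestamped arterial blood-gas
#' measurements with a one-row-per-patient covariate/outcome table. Time is
#' measured in hours since ICU admission (admission = 0); all analysis
#' windows are anchored there.
#'
#' @param measurements data.frame with columns `patient_id`, `t_hours`,
#'   `glucose_mgdl`, `lactate_mmoll` (the analyte columns may contain `NA`
#'   where only one analyte was measured, but not both `NA` in one row).
#' @param covariates data.frame with columns `patient_id`, `outcome`
#'   (1 = ICU non-survivor), `icu_los_hours`, `age`, `sex`, `bmi`, `gcs`,
#'   `isolated_tbi`, `hypertension`, `ckd`, `saps2`; extra columns (e.g.
#'   `iss`, `non_c_sofa`, `diabetes`) are carried along.
#' @param meta optional named list of provenance notes (source file,
#'   simulation seed/config).
#'
#' @return An object of class `bg_cohort`: a list with elements
#'   `measurements`, `covariates`, `meta`. Measurements are sorted by
#'   patient and time.
#'
#' @details Validation is total: duplicate timestamps within a patient,
#' non-positive analyte values, measurements past `icu_los_hours`,
#' measurement rows for patients absent from the covariate table, or
#' non-binary outcomes all raise typed errors (`icumet_integrity_error` /
#' `icumet_format_error`). Rows with both analytes missing are rejected
#' here; [read_cohort()] drops them with a logged count before
#' construction.
#'
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
bg_cohort <- function(measurements, covariates, meta = list()) {
  measurements <- as.data.frame(measurements)
  covariates <- as.data.frame(covariates)
  miss <- setdiff(MEAS_COLS, names(measurements))
  if (length(miss) > 0L) {
    stop_icumet("format", "measurement table lacks column(s): ",
                paste(miss, collapse = ", "))
  }
  miss <- setdiff(COV_COLS, names(covariates))
  if (length(miss) > 0L) {
    stop_icumet("format", "covariate table lacks column(s): ",
                paste(miss, collapse = ", "))
  }
  measurements$patient_id <- as.character(measurements$patient_id)
  covariates$patient_id <- as.character(covariates$patient_id)
  if (anyDuplicated(covariates$patient_id)) {
    stop_icumet("integrity", "duplicate patient_id in covariate table: ",
                paste(unique(covariates$patient_id[
                  duplicated(covariates$patient_id)]), collapse = ", "))
  }
  unknown <- setdiff(unique(measurements$patient_id), covariates$patient_id)
  if (length(unknown) > 0L) {
    stop_icumet("integrity",
                "measurements for patient(s) absent from covariate table: ",
                paste(unknown, collapse = ", "))
  }
  if (nrow(measurements) > 0L) {
    both_na <- is.na(measurements$glucose_mgdl) &
      is.na(measurements$lactate_mmoll)
    if (any(both_na)) {
      stop_icumet("format", sum(both_na),
                  " measurement row(s) with both analytes missing")
    }
    if (any(!is.finite(measurements$t_hours)) || any(measurements$t_hours < 0)) {
      stop_icumet("format", "t_hours must be finite and >= 0")
    }
    bad_g <- !is.na(measurements$glucose_mgdl) & measurements$glucose_mgdl <= 0
    bad_l <- !is.na(measurements$lactate_mmoll) & measurements$lactate_mmoll <= 0
    if (any(bad_g) || any(bad_l)) {
      stop_icumet("format", "analyte values must be > 0 when present")
    }
    measurements <- measurements[order(measurements$patient_id,
                                       measurements$t_hours), , drop = FALSE]
    rownames(measurements) <- NULL
    dup <- stats::ave(measurements$t_hours, measurements$patient_id,
                      FUN = function(t) duplicated(t))
    if (any(dup > 0)) {
      ids <- unique(measurements$patient_id[dup > 0])
      stop_icumet("integrity", "duplicate timestamps for patient(s): ",
                  paste(ids, collapse = ", "))
    }
  }
  if (any(!is.finite(covariates$icu_los_hours)) ||
      any(covariates$icu_los_hours <= 0)) {
    stop_icumet("format", "icu_los_hours must be finite and > 0")
  }
  if (!all(covariates$outcome %in% c(0, 1))) {
    stop_icumet("format", "outcome must be 0 (survivor) or 1 (non-survivor)")
  }
  if (nrow(measurements) > 0L) {
    los <- covariates$icu_los_hours[match(measurements$patient_id,
                                          covariates$patient_id)]
    late <- measurements$t_hours > los
    if (any(late)) {
      ids <- unique(measurements$patient_id[late])
      stop_icumet("integrity",
                  "measurements after icu_los_hours for patient(s): ",
                  paste(ids, collapse = ", "))
    }
  }
  structure(list(measurements = measurements, covariates = covariates,
                 meta = meta),
            class = "bg_cohort")
}

#' @export
print.bg_cohort <- function(x, ...) {
  cat(sprintf("<bg_cohort> %d patients, %d measurements\n",
              nrow(x$covariates), nrow(x$measurements)))
  if (nrow(x$covariates) > 0L) {
    cat(sprintf("  non-survivors: %d (%.1f%%)\n", sum(x$covariates$outcome),
                100 * mean(x$covariates$outcome)))
    cat(sprintf("  ICU LOS [h]: median %.1f (range %.1f-%.1f)\n",
                median(x$covariates$icu_los_hours),
                min(x$covariates$icu_los_hours),
                max(x$covariates$icu_los_hours)))
  }
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `bg_cohort`
#' @return integer patient count
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "bg_cohort"))
  nrow(cohort$covariates)
}

#' Extract one patient's record
#'
#' @param cohort a `bg_cohort`
#' @param patient_id patient identifier
#' @return list with `patient_id`, `outcome`, `icu_los`, `covariates`
#'   (one-row data.frame) and `series` (measurement data.frame sorted by
#'   time)
#' @export
patient_record <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "bg_cohort"))
  i <- match(as.character(patient_id), cohort$covariates$patient_id)
  if (is.na(i)) {
    stop_icumet("integrity", "unknown patient_id: ", patient_id)
  }
  cov <- cohort$covariates[i, , drop = FALSE]
  ser <- cohort$measurements[
    cohort$measurements$patient_id == cov$patient_id, , drop = FALSE]
  list(patient_id = cov$patient_id, outcome = cov$outcome,
       icu_los = cov$icu_los_hours, covariates = cov, series = ser)
}

#' Read a cohort from its two-table CSV representation
#'
#' @param measurements_path CSV with columns `patient_id`, `t_hours`,
#'   `glucose_mgdl`, `lactate_mmoll` (empty cell = analyte not measured)
#' @param covariates_path CSV with one row per patient (see [bg_cohort()])
#' @return validated `bg_cohort`; rows with both analytes missing are
#'   dropped with a message stating the count, and the count is recorded in
#'   `meta$dropped_rows`
#' @export
read_cohort <- function(measurements_path, covariates_path) {
  meas <- read.csv(measurements_path, stringsAsFactors = FALSE,
                   colClasses = c(patient_id = "character"))
  covs <- read.csv(covariates_path, stringsAsFactors = FALSE,
                   colClasses = c(patient_id = "character"))
  miss <- setdiff(MEAS_COLS, names(meas))
  if (length(miss) > 0L) {
    stop_icumet("format", "measurement file lacks column(s): ",
                paste(miss, collapse = ", "))
  }
  dropped <- 0L
  if (nrow(meas) > 0L) {
    both_na <- is.na(meas$glucose_mgdl) & is.na(meas$lactate_mmoll)
    dropped <- sum(both_na)
    if (dropped > 0L) {
      message("read_cohort: dropped ", dropped,
              " row(s) with both analytes missing")
      meas <- meas[!both_na, , drop = FALSE]
    }
  }
  bg_cohort(meas, covs,
            meta = list(measurements_path = measurements_path,
                        covariates_path = covariates_path,
                        dropped_rows = dropped))
}

#' Write a cohort to the two-table CSV representation
#'
#' Emits `measurements.csv` and `covariates.csv` in `out_dir`, the same
#' format [read_cohort()] accepts, so that write followed by read is the
#' identity on valid cohorts (up to column order of extra covariates).
#'
#' @param cohort a `bg_cohort`
#' @param out_dir output directory (created if absent)
#' @return invisibly, a named character vector of the two file paths
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "bg_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_icumet("io", "cannot create directory: ", out_dir)
  }
  paths <- c(measurements = file.path(out_dir, "measurements.csv"),
             covariates = file.path(out_dir, "covariates.csv"))
  write.csv(cohort$measurements, paths["measurements"], row.names = FALSE,
            na = "")
  write.csv(cohort$covariates, paths["covariates"], row.names = FALSE,
            na = "")
  invisible(paths)
}

stop_icumet <- function(class, ...) {
  stop(structure(class = c(paste0("icumet_", class, "_error"),
                           "icumet_error", "error", "condition"),
                 list(message = paste0(..., collapse = ""),
                      call = sys.call(-1))))
}
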