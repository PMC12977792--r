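#' Eligibility rules
#'
#' The standard screening cascade: (i) confirmed TBI (when a `tbi` flag
#' column is present), (ii) ICU stay of at least 72 h, (iii) at least 4
#' blood-gas analyses per day on average, (iv) adult age, (v) no diabetes
#' mellitus (when a `diabetes` flag column is present). Exclusions are
#' tallied in this order; the first matching criterion claims the
#' exclusion.
#'
#' @param min_age minimum age in years (default 18)
#' @param min_los minimum ICU stay in hours (default 72)
#' @param min_daily_bga minimum average blood-gas analyses per day
#'   (default 4)
#' @param require_tbi apply criterion (i) using covariate column `tbi`
#' @param exclude_diabetes apply criterion (v) using covariate column
#'   `diabetes`
#' @return an `eligibility_rules` list
#' @export
eligibility_rules <- function(min_age = 18, min_los = 72, min_daily_bga = 4,
                              require_tbi = FALSE, exclude_diabetes = FALSE) {
  stopifnot(min_age > 0, min_los > 0, min_daily_bga > 0)
  structure(list(min_age = min_age, min_los = min_los,
                 min_daily_bga = min_daily_bga, require_tbi = require_tbi,
                 exclude_diabetes = exclude_diabetes),
            class = "eligibility_rules")
}

#' Apply eligibility screening to a cohort
#'
#' @param cohort a `bg_cohort`
#' @param rules an [eligibility_rules()]
#' @return list with `cohort` (eligible patients only) and `tally`
#'   (named exclusion counts per criterion, in screening order)
#' @export
apply_eligibility <- function(cohort, rules = eligibility_rules()) {
  stopifnot(inherits(cohort, "bg_cohort"), inherits(rules, "eligibility_rules"))
  cov <- cohort$covariates
  if (rules$require_tbi && !"tbi" %in% names(cov)) {
    stop_icumet("config", "require_tbi is active but covariate 'tbi' is absent")
  }
  if (rules$exclude_diabetes && !"diabetes" %in% names(cov)) {
    stop_icumet("config",
                "exclude_diabetes is active but covariate 'diabetes' is absent")
  }
  n_meas <- table(factor(cohort$measurements$patient_id,
                         levels = cov$patient_id))
  daily_bga <- as.numeric(n_meas) / (cov$icu_los_hours / 24)

  reason <- rep(NA_character_, nrow(cov))
  claim <- function(cond, label) {
    hit <- is.na(reason) & cond
    reason[hit] <<- label
  }
  if (rules$require_tbi) claim(cov$tbi == 0, "no_tbi")
  claim(cov$icu_los_hours < rules$min_los, "los_lt_72h")
  claim(daily_bga < rules$min_daily_bga, "lt_4_bga_per_day")
  claim(cov$age < rules$min_age, "age_lt_18")
  if (rules$exclude_diabetes) claim(cov$diabetes == 1, "diabetes")

  labels <- c(if (rules$require_tbi) "no_tbi", "los_lt_72h",
              "lt_4_bga_per_day", "age_lt_18",
              if (rules$exclude_diabetes) "diabetes")
  tally <- vapply(labels, function(l) sum(reason == l, na.rm = TRUE),
                  integer(1))
  keep_ids <- cov$patient_id[is.na(reason)]
  out <- bg_cohort(
    cohort$measurements[cohort$measurements$patient_id %in% keep_ids, ,
                        drop = FALSE],
    cov[is.na(reason), , drop = FALSE],
    meta = c(cohort$meta, list(eligibility_tally = tally)))
  list(cohort = out, tally = tally)
}

#' Matching specification
#'
#' 1:2 nearest-neighbor propensity score matching without replacement,
#' with a caliper of 0.2 standard deviations of the logit propensity
#' score and a post-matching balance target of SMD < 0.10.
#'
#' @param ratio controls per case (default 2)
#' @param caliper_mult caliper width as a multiple of the SD of the logit
#'   propensity score (default 0.2)
#' @param covariates matching covariates (pre-exposure, available at
#'   admission)
#' @param smd_threshold balance target for standardized mean differences
#' @return a `match_spec` list
#' @export
match_spec <- function(ratio = 2, caliper_mult = 0.2,
                       covariates = c("age", "sex", "bmi", "gcs",
                                      "isolated_tbi", "hypertension",
                                      "ckd", "saps2"),
                       smd_threshold = 0.10) {
  stopifnot(ratio >= 1, caliper_mult > 0, length(covariates) >= 1,
            smd_threshold > 0)
  structure(list(ratio = as.integer(ratio), caliper_mult = caliper_mult,
                 covariates = covariates, smd_threshold = smd_threshold),
            class = "match_spec")
}

#' Estimate propensity scores
#'
#' Maximum-likelihood logistic regression of the outcome on pre-exposure
#' covariates. Covariates with zero variance are dropped with a warning;
#' missing covariate values or perfect separation raise errors.
#'
#' @param cohort a `bg_cohort`
#' @param covariates covariate names (columns of the covariate table)
#' @return data.frame with `patient_id`, `pscore` (in (0,1)) and `logit`
#' @export
estimate_propensity <- function(cohort,
                                covariates = match_spec()$covariates) {
  stopifnot(inherits(cohort, "bg_cohort"))
  cov <- cohort$covariates
  missing_cols <- setdiff(covariates, names(cov))
  if (length(missing_cols) > 0L) {
    stop_icumet("config", "covariate(s) absent from cohort: ",
                paste(missing_cols, collapse = ", "))
  }
  X <- cov[, covariates, drop = FALSE]
  if (anyNA(X)) {
    stop_icumet("format", "missing covariate values; propensity estimation ",
                "requires complete cases")
  }
  constant <- vapply(X, function(x) length(unique(x)) == 1L, logical(1))
  if (any(constant)) {
    warning("dropping zero-variance covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
    X <- X[, !constant, drop = FALSE]
  }
  dat <- cbind(data.frame(.outcome = cov$outcome), X)
  fit <- suppressWarnings(
    glm(.outcome ~ ., data = dat, family = binomial()))
  p <- fitted(fit)
  if (any(p < 1e-10) || any(p > 1 - 1e-10)) {
    stop_icumet("fit", "propensity model shows (quasi-)separation: fitted ",
                "probabilities of 0 or 1")
  }
  data.frame(patient_id = cov$patient_id, pscore = as.numeric(p),
             logit = qlogis(as.numeric(p)), stringsAsFactors = FALSE)
}

#' Nearest-neighbor caliper matching
#'
#' Greedy 1:`ratio` nearest-neighbor matching without replacement on the
#' logit propensity score. Cases (outcome = 1) are processed in
#' descending propensity score (hardest to match first); each receives up
#' to `ratio` unused controls nearest in `|logit difference|` within the
#' caliper `caliper_mult * SD(logit)` (SD over all patients). Ties are
#' broken by the smaller control id. Cases with no in-caliper control are
#' recorded unmatched. The procedure is deterministic.
#'
#' @param cohort a `bg_cohort`
#' @param spec a [match_spec()]
#' @param propensity optional precomputed result of
#'   [estimate_propensity()]; estimated if `NULL`
#' @return a `matched_cohort`: list with `sets` (data.frame `set_id`,
#'   `patient_id`, `role`, `pscore`, `logit`), `unmatched` (data.frame
#'   `patient_id`, `reason`), `caliper`, `propensity`, `balance`
#'   (per-covariate SMD before/after, see [balance_report()]), `spec`
#' @export
match_cases <- function(cohort, spec = match_spec(), propensity = NULL) {
  stopifnot(inherits(cohort, "bg_cohort"), inherits(spec, "match_spec"))
  if (is.null(propensity)) {
    propensity <- estimate_propensity(cohort, spec$covariates)
  }
  cov <- cohort$covariates
  ps <- propensity[match(cov$patient_id, propensity$patient_id), ]
  if (anyNA(ps$logit)) {
    stop_icumet("integrity", "propensity scores missing for some patients")
  }
  cases <- which(cov$outcome == 1)
  controls <- which(cov$outcome == 0)
  if (length(cases) == 0L || length(controls) == 0L) {
    stop_icumet("format", "matching needs at least one case and one control")
  }
  caliper <- spec$caliper_mult * sd(ps$logit)

  case_order <- cases[order(-ps$pscore[cases], cov$patient_id[cases])]
  used <- logical(nrow(cov))
  sets <- list(); unmatched <- list(); set_id <- 0L
  for (i in case_order) {
    avail <- controls[!used[controls]]
    d <- abs(ps$logit[avail] - ps$logit[i])
    ok <- avail[d <= caliper]
    if (length(ok) == 0L) {
      unmatched[[length(unmatched) + 1L]] <-
        data.frame(patient_id = cov$patient_id[i],
                   reason = "no control in caliper",
                   stringsAsFactors = FALSE)
      next
    }
    dd <- abs(ps$logit[ok] - ps$logit[i])
    ord <- order(dd, cov$patient_id[ok])
    pick <- ok[ord][seq_len(min(spec$ratio, length(ok)))]
    used[pick] <- TRUE
    set_id <- set_id + 1L
    members <- c(i, pick)
    sets[[set_id]] <- data.frame(
      set_id = set_id, patient_id = cov$patient_id[members],
      role = c("case", rep("control", length(pick))),
      pscore = ps$pscore[members], logit = ps$logit[members],
      stringsAsFactors = FALSE)
  }
  sets_df <- if (length(sets)) do.call(rbind, sets) else
    data.frame(set_id = integer(0), patient_id = character(0),
               role = character(0), pscore = numeric(0), logit = numeric(0))
  unmatched_df <- if (length(unmatched)) do.call(rbind, unmatched) else
    data.frame(patient_id = character(0), reason = character(0))
  out <- structure(list(sets = sets_df, unmatched = unmatched_df,
                        caliper = caliper, propensity = propensity,
                        spec = spec, cohort = cohort),
                   class = "matched_cohort")
  out$balance <- balance_report(out)
  out
}

#' @export
print.matched_cohort <- function(x, ...) {
  n_sets <- length(unique(x$sets$set_id))
  cat(sprintf("<matched_cohort> %d sets (%d cases matched, %d unmatched)\n",
              n_sets, n_sets, nrow(x$unmatched)))
  cat(sprintf("  caliper: %.4f (logit scale)\n", x$caliper))
  if (!is.null(x$balance)) {
    cat(sprintf("  covariates within SMD threshold after matching: %d/%d\n",
                sum(x$balance$pass), nrow(x$balance)))
  }
  invisible(x)
}

#' Standardized mean difference
#'
#' Continuous covariates: `|mean1 - mean0| / sqrt((var1 + var0) / 2)`
#' with sample variances. Binary covariates: the analogous formula on
#' proportions, `|p1 - p0| / sqrt((p1 (1 - p1) + p0 (1 - p0)) / 2)`.
#' Zero pooled variance with unequal means yields `Inf`.
#'
#' @param x covariate values
#' @param group binary group indicator (1 = case)
#' @return the SMD (>= 0)
#' @export
standardized_mean_difference <- function(x, group) {
  stopifnot(length(x) == length(group), all(group %in% c(0, 1)))
  x1 <- x[group == 1]; x0 <- x[group == 0]
  binary <- all(x %in% c(0, 1))
  if (binary) {
    p1 <- mean(x1); p0 <- mean(x0)
    pooled <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
    num <- abs(p1 - p0)
  } else {
    pooled <- (var(x1) + var(x0)) / 2
    num <- abs(mean(x1) - mean(x0))
  }
  if (is.na(pooled)) return(NA_real_)   # a group with < 2 observations
  if (pooled == 0) {
    return(if (num == 0) 0 else Inf)
  }
  num / sqrt(pooled)
}

#' Covariate balance before and after matching
#'
#' Per matching covariate, the SMD between cases and controls computed on
#' the full cohort (before) and on matched patients only (after), with a
#' pass flag against the spec's SMD threshold. The table is
#' machine-readable and plot-ready (Love-plot data).
#'
#' @param matched a `matched_cohort`
#' @return data.frame with `covariate`, `smd_before`, `smd_after`, `pass`
#' @export
balance_report <- function(matched) {
  stopifnot(inherits(matched, "matched_cohort"))
  cov <- matched$cohort$covariates
  covariates <- matched$spec$covariates
  matched_ids <- matched$sets$patient_id
  sub <- cov[cov$patient_id %in% matched_ids, , drop = FALSE]
  smd_safe <- function(x, g) {
    if (length(unique(g)) < 2L) return(NA_real_)
    standardized_mean_difference(x, g)
  }
  out <- data.frame(
    covariate = covariates,
    smd_before = vapply(covariates, function(v)
      smd_safe(cov[[v]], cov$outcome), numeric(1)),
    smd_after = vapply(covariates, function(v)
      smd_safe(sub[[v]], sub$outcome), numeric(1)),
    stringsAsFactors = FALSE)
  out$pass <- !is.na(out$smd_after) &
    out$smd_after < matched$spec$smd_threshold
  rownames(out) <- NULL
  out
}
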