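#' Construct a marker series
#'
#' A marker series is the (time, value) curve of one metabolic marker for
#' one patient: glucose (mg/dL), lactate (mmol/L) or their molar
#' glucose-lactate ratio (dimensionless). Time is hours since ICU
#' admission.
#'
#' @param t numeric vector of times (hours, finite, >= 0, strictly
#'   increasing)
#' @param value numeric vector of marker values (> 0), same length as `t`
#' @param marker one of `"glucose"`, `"lactate"`, `"ratio"`
#' @return a `marker_series`: data.frame with columns `t`, `value` and a
#'   `marker` attribute
#' @export
marker_series <- function(t, value, marker = c("glucose", "lactate", "ratio")) {
  marker <- match.arg(marker)
  if (length(t) != length(value)) {
    stop_icumet("format", "t and value lengths differ")
  }
  if (length(t) < 1L) stop_icumet("format", "marker series needs >= 1 point")
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_icumet("format", "times must be finite and >= 0")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop_icumet("format", "times must be strictly increasing")
  }
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop_icumet("format", "marker values must be finite and > 0")
  }
  structure(data.frame(t = as.numeric(t), value = as.numeric(value)),
            marker = marker, class = c("marker_series", "data.frame"))
}

#' Molar glucose-lactate ratio series
#'
#' Forms one ratio point per timestamp at which both analytes were
#' measured (blood-gas panels report both from one sample, so in practice
#' the intersection is dense). Glucose is converted from mg/dL to mmol/L
#' by dividing by 18; the ratio is glucose \[mmol/L\] / lactate \[mmol/L\].
#' No cross-interpolation between analytes is performed.
#'
#' @param glucose `marker_series` of glucose (mg/dL)
#' @param lactate `marker_series` of lactate (mmol/L)
#' @return `marker_series` of the dimensionless molar ratio
#' @export
ratio_series <- function(glucose, lactate) {
  stopifnot(inherits(glucose, "marker_series"),
            inherits(lactate, "marker_series"))
  common <- intersect(glucose$t, lactate$t)
  if (length(common) == 0L) {
    stop_icumet("empty_series",
                "no common timestamps between glucose and lactate")
  }
  common <- sort(common)
  g <- glucose$value[match(common, glucose$t)]
  l <- lactate$value[match(common, lactate$t)]
  marker_series(common, (g / 18) / l, marker = "ratio")
}

#' Admission value (AB)
#'
#' The first recorded value no later than `window` hours after ICU
#' admission (boundary inclusive).
#'
#' @param series a `marker_series`
#' @param window admission window in hours (default 6)
#' @return the earliest value with `t <= window`, or `NA_real_` if the
#'   first measurement falls later
#' @export
admission_value <- function(series, window = 6) {
  stopifnot(inherits(series, "marker_series"), window > 0)
  if (series$t[1L] <= window) series$value[1L] else NA_real_
}

#' Arithmetic mean (MB)
#'
#' Unweighted mean of all measurements, irrespective of their timing.
#' Biased toward phases of frequent sampling; compare
#' [time_weighted_average()].
#'
#' @param series a `marker_series`
#' @return numeric mean
#' @export
mean_value <- function(series) {
  stopifnot(inherits(series, "marker_series"))
  mean(series$value)
}

#' Time-weighted average (TWA) by the trapezoidal rule
#'
#' The area under the piecewise-linear measurement curve divided by the
#' observation time, so that each value is weighted by how long it
#' plausibly persisted rather than by how often it was sampled.
#'
#' Window boundaries falling strictly inside the sampled range are
#' evaluated by linear interpolation; parts of the window outside the
#' sampled range contribute nothing and shrink the denominator to the
#' covered span. With a single point in the window the TWA is that value.
#'
#' @param series a `marker_series`
#' @param t_start window start (hours, default 0)
#' @param t_end window end (hours); default the end of the series
#' @return numeric TWA over the covered span
#' @export
time_weighted_average <- function(series, t_start = 0, t_end = NULL) {
  stopifnot(inherits(series, "marker_series"))
  if (is.null(t_end)) t_end <- series$t[length(series$t)]
  if (t_start >= t_end && !(t_start == t_end && t_start %in% series$t)) {
    stop_icumet("format", "t_start must be < t_end")
  }
  lo <- max(t_start, series$t[1L])
  hi <- min(t_end, series$t[length(series$t)])
  if (lo > hi) {
    stop_icumet("no_data", "window [", t_start, ", ", t_end,
                "] is disjoint from the sampled range")
  }
  if (lo == hi) {
    return(approx(series$t, series$value, xout = lo)$y)
  }
  inner <- series$t > lo & series$t < hi
  tt <- c(lo, series$t[inner], hi)
  vv <- c(approx(series$t, series$value, xout = lo)$y,
          series$value[inner],
          approx(series$t, series$value, xout = hi)$y)
  area <- sum(diff(tt) * (head(vv, -1) + vv[-1]) / 2)
  area / (hi - lo)
}

#' Interval TWA sequence
#'
#' Partitions time into consecutive windows `[k*interval, (k+1)*interval)`
#' anchored at admission and computes the TWA in each. Windows with no
#' coverage yield `NA`. Daily (24 h) bins feed the trajectory model's
#' primary analysis; 6 h bins its spline-based visualization scale.
#'
#' @param series a `marker_series`
#' @param interval window width in hours (e.g. 6 or 24)
#' @param t_max end of the partitioned span (hours); default the last
#'   measurement time. The number of windows is `ceiling(t_max/interval)`.
#' @return data.frame with columns `interval` (0-based index), `t_start`,
#'   `t_end`, `twa`
#' @export
twa_by_interval <- function(series, interval, t_max = NULL) {
  stopifnot(inherits(series, "marker_series"), interval > 0)
  if (is.null(t_max)) t_max <- series$t[length(series$t)]
  n <- max(1L, as.integer(ceiling(t_max / interval - 1e-12)))
  out <- data.frame(interval = seq_len(n) - 1L)
  out$t_start <- out$interval * interval
  out$t_end <- out$t_start + interval
  t1 <- series$t[1L]
  tn <- series$t[length(series$t)]
  out$twa <- vapply(seq_len(n), function(k) {
    lo <- out$t_start[k]; hi <- out$t_end[k]
    lo_c <- max(lo, t1); hi_c <- min(hi, tn)
    if (lo_c > hi_c) return(NA_real_)          # no coverage
    if (lo_c == hi_c && lo_c >= hi) return(NA_real_)  # touches right edge only
    time_weighted_average(series, lo, hi)
  }, numeric(1))
  out
}

#' Coefficient of variation (CV)
#'
#' Sample standard deviation (n-1 denominator) divided by the arithmetic
#' mean, as a percentage.
#'
#' @param series a `marker_series` with >= 2 points
#' @return CV in percent
#' @export
coefficient_of_variation <- function(series) {
  stopifnot(inherits(series, "marker_series"))
  if (nrow(series) < 2L) {
    stop_icumet("insufficient_data", "CV needs >= 2 measurements")
  }
  100 * sd(series$value) / mean(series$value)
}

#' Lactate clearance (LC)
#'
#' Percentage change from the admission value at a fixed horizon,
#' `100 * (AB - L_h) / AB`; positive values indicate decline (clearance),
#' negative values a rise.
#'
#' Two readings of the horizon concentration `L_h` are supported:
#' \describe{
#'   \item{`raw`}{the last observed value at `t <= horizon`; requires a
#'     second observation beyond the admission value, else `NA`.}
#'   \item{`interpolated`}{linear interpolation between the nearest
#'     measurements bracketing the horizon (the observed value itself if
#'     one falls exactly there); requires a measurement at or after the
#'     horizon, else `NA`.}
#' }
#'
#' @param series lactate `marker_series`
#' @param horizon horizon in hours (6, 24 or 72 in the standard grid)
#' @param mode `"raw"` or `"interpolated"`
#' @param admission_window admission-value window (hours, default 6)
#' @return clearance in percent, or `NA_real_` when `L_h` cannot be formed
#' @export
lactate_clearance <- function(series, horizon,
                              mode = c("raw", "interpolated"),
                              admission_window = 6) {
  stopifnot(inherits(series, "marker_series"), horizon > 0)
  mode <- match.arg(mode)
  ab <- admission_value(series, window = admission_window)
  if (is.na(ab)) return(NA_real_)
  t_ab <- series$t[1L]
  if (mode == "raw") {
    in_win <- which(series$t <= horizon)
    if (length(in_win) == 0L) return(NA_real_)
    last <- max(in_win)
    if (series$t[last] == t_ab) return(NA_real_)  # no second point
    lh <- series$value[last]
  } else {
    if (horizon %in% series$t) {
      lh <- series$value[match(horizon, series$t)]
    } else {
      before <- which(series$t < horizon)
      after <- which(series$t > horizon)
      if (length(before) == 0L || length(after) == 0L) return(NA_real_)
      i <- max(before); j <- min(after)
      w <- (horizon - series$t[i]) / (series$t[j] - series$t[i])
      lh <- (1 - w) * series$value[i] + w * series$value[j]
    }
  }
  100 * (ab - lh) / ab
}

#' Default TUDR configuration
#'
#' Glycemic target range 70-180 mg/dL; candidate period lengths 1, 2, 3,
#' 4, 6, 8 and 12 h; a candidate qualifies when the cohort median of the
#' per-patient occupied-period fraction is at least 95%.
#'
#' @param target_low lower glucose target (mg/dL)
#' @param target_high upper glucose target (mg/dL)
#' @param candidate_periods candidate period lengths (hours, ascending)
#' @param coverage_threshold required median occupied-period fraction
#' @return a `tudr_config` list
#' @export
tudr_config <- function(target_low = 70, target_high = 180,
                        candidate_periods = c(1, 2, 3, 4, 6, 8, 12),
                        coverage_threshold = 0.95) {
  stopifnot(target_low > 0, target_low < target_high,
            length(candidate_periods) >= 1,
            !is.unsorted(candidate_periods, strictly = TRUE),
            coverage_threshold > 0, coverage_threshold <= 1)
  structure(list(target_low = target_low, target_high = target_high,
                 candidate_periods = candidate_periods,
                 coverage_threshold = coverage_threshold),
            class = "tudr_config")
}

period_index <- function(t, period, icu_los) {
  # partition [0, icu_los) anchored at admission; a sample exactly at
  # discharge is folded into the trailing period
  i <- floor(t / period)
  n <- ceiling(icu_los / period - 1e-12)
  pmin(i, n - 1)
}

#' Adaptive TUDR period selection
#'
#' Scans the candidate period lengths in ascending order and returns the
#' shortest for which the cohort median per-patient coverage (fraction of
#' equal-length periods over `[0, icu_los)` containing at least one
#' glucose value) reaches the configured threshold. If none qualifies the
#' largest candidate is returned with a warning.
#'
#' @param cohort a `bg_cohort`; every patient must have >= 1 glucose value
#' @param config a [tudr_config()]
#' @return selected period length in hours
#' @export
select_tudr_period <- function(cohort, config = tudr_config()) {
  stopifnot(inherits(cohort, "bg_cohort"), inherits(config, "tudr_config"))
  if (n_patients(cohort) == 0L) stop_icumet("format", "empty cohort")
  meas <- cohort$measurements[!is.na(cohort$measurements$glucose_mgdl), ,
                              drop = FALSE]
  ids <- cohort$covariates$patient_id
  if (!all(ids %in% meas$patient_id)) {
    stop_icumet("insufficient_data",
                "patient(s) without any glucose measurement: ",
                paste(setdiff(ids, meas$patient_id), collapse = ", "))
  }
  los <- setNames(cohort$covariates$icu_los_hours, ids)
  t_by_pat <- split(meas$t_hours, meas$patient_id)
  for (p in config$candidate_periods) {
    cov_frac <- vapply(ids, function(id) {
      n <- ceiling(los[[id]] / p - 1e-12)
      occ <- length(unique(period_index(t_by_pat[[id]], p, los[[id]])))
      occ / n
    }, numeric(1))
    if (median(cov_frac) >= config$coverage_threshold) return(p)
  }
  warning("no candidate period reaches ",
          100 * config$coverage_threshold,
          "% median coverage; falling back to the largest candidate (",
          max(config$candidate_periods), " h)")
  max(config$candidate_periods)
}

#' Time-unified dysglycemic rate (TUDR)
#'
#' The ICU stay `[0, icu_los)` is divided into consecutive equal-length
#' periods anchored at admission (a trailing partial period counts when
#' occupied). A period is dysglycemic if any glucose value within it lies
#' outside the target range. TUDR is the percentage of dysglycemic
#' periods among periods containing at least one measurement, so the
#' metric is insensitive to sampling frequency within a period.
#'
#' @param series glucose `marker_series` (mg/dL)
#' @param period period length in hours (choose via
#'   [select_tudr_period()])
#' @param icu_los observation span in hours; default the last measurement
#'   time
#' @param config a [tudr_config()] supplying the target range
#' @return TUDR in percent (0-100)
#' @export
tudr <- function(series, period, icu_los = NULL, config = tudr_config()) {
  stopifnot(inherits(series, "marker_series"), period > 0,
            inherits(config, "tudr_config"))
  if (nrow(series) == 0L) {
    stop_icumet("insufficient_data", "no glucose measurements")
  }
  if (is.null(icu_los)) icu_los <- series$t[length(series$t)]
  if (icu_los <= 0) icu_los <- period
  idx <- period_index(series$t, period, icu_los)
  out_of_range <- series$value < config$target_low |
    series$value > config$target_high
  occupied <- unique(idx)
  dys <- unique(idx[out_of_range])
  100 * length(dys) / length(occupied)
}

marker_from_record <- function(record, marker) {
  ser <- record$series
  col <- switch(marker, glucose = "glucose_mgdl", lactate = "lactate_mmoll")
  keep <- !is.na(ser[[col]])
  if (!any(keep)) return(NULL)
  marker_series(ser$t_hours[keep], ser[[col]][keep], marker = marker)
}

index_set <- function(series, icu_los, tudr_period = NULL,
                      config = tudr_config()) {
  marker <- attr(series, "marker")
  n <- nrow(series)
  set <- list(
    marker = marker,
    ab = admission_value(series),
    mb = mean_value(series),
    twa = if (n >= 2L) time_weighted_average(series) else series$value[1L],
    twa_72h = tryCatch(time_weighted_average(series, 0, 72),
                       icumet_no_data_error = function(e) NA_real_),
    cv = if (n >= 2L) coefficient_of_variation(series) else NA_real_
  )
  if (marker == "glucose" && !is.null(tudr_period)) {
    set$tudr <- tudr(series, tudr_period, icu_los = icu_los, config = config)
  }
  if (marker == "lactate") {
    set$lc <- lapply(setNames(c(6, 24, 72), c("h6", "h24", "h72")),
                     function(h) {
                       c(raw = lactate_clearance(series, h, "raw"),
                         ip = lactate_clearance(series, h, "interpolated"))
                     })
  }
  structure(set, class = "index_set")
}

#' Compute all metabolic indices for one patient
#'
#' Populates the full index grid for the three markers: admission value
#' (AB), mean (MB), time-weighted average over the full stay (TWA) and the
#' first 72 h (72h-TWA), coefficient of variation (CV) for glucose,
#' lactate and the molar glucose-lactate ratio; TUDR for glucose only; raw
#' and interpolated lactate clearance at 6/24/72 h for lactate only.
#' Indices that cannot be formed (e.g. no measurement within the
#' admission window) are `NA`, never fabricated.
#'
#' @param record a patient record from [patient_record()]
#' @param tudr_period TUDR period length in hours (cohort-level choice
#'   from [select_tudr_period()]); `NULL` skips TUDR
#' @param config a [tudr_config()]
#' @return named list of `index_set` objects for `glucose`, `lactate`,
#'   `ratio`
#' @export
compute_index_sets <- function(record, tudr_period = NULL,
                               config = tudr_config()) {
  glu <- marker_from_record(record, "glucose")
  lac <- marker_from_record(record, "lactate")
  if (is.null(glu) || is.null(lac)) {
    stop_icumet("insufficient_data", "patient ", record$patient_id,
                " lacks glucose or lactate measurements")
  }
  rat <- tryCatch(ratio_series(glu, lac),
                  icumet_empty_series_error = function(e) NULL)
  sets <- list(glucose = index_set(glu, record$icu_los, tudr_period, config),
               lactate = index_set(lac, record$icu_los))
  if (!is.null(rat)) sets$ratio <- index_set(rat, record$icu_los)
  sets
}

#' Per-patient index table for a cohort
#'
#' One row per patient with the full index grid under the standard
#' abbreviations (columns `abg`, `mbg`, `twag`, `twag_72h`, `cvg`, `tudr`,
#' `abl`, `mbl`, `twal`, `twal_72h`, `cvl`, `lc6_raw`, `lc6_ip`,
#' `lc24_raw`, `lc24_ip`, `lc72_raw`, `lc72_ip`, `abgl`, `mbgl`, `twagl`,
#' `twagl_72h`, `cvgl`), plus `patient_id`, `outcome` and the selected
#' `tudr_period`.
#'
#' @param cohort a `bg_cohort`
#' @param tudr_period period length in hours; `NULL` (default) selects it
#'   adaptively via [select_tudr_period()]
#' @param config a [tudr_config()]
#' @return data.frame of indices; missing indices are `NA`
#' @export
cohort_index_table <- function(cohort, tudr_period = NULL,
                               config = tudr_config()) {
  stopifnot(inherits(cohort, "bg_cohort"))
  if (is.null(tudr_period)) {
    tudr_period <- select_tudr_period(cohort, config)
  }
  rows <- lapply(cohort$covariates$patient_id, function(id) {
    rec <- patient_record(cohort, id)
    s <- compute_index_sets(rec, tudr_period = tudr_period, config = config)
    g <- s$glucose; l <- s$lactate; r <- s$ratio
    na_if_null <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else x
    data.frame(
      patient_id = id, outcome = rec$outcome, tudr_period = tudr_period,
      abg = na_if_null(g$ab), mbg = g$mb, twag = g$twa,
      twag_72h = g$twa_72h, cvg = na_if_null(g$cv), tudr = na_if_null(g$tudr),
      abl = na_if_null(l$ab), mbl = l$mb, twal = l$twa,
      twal_72h = l$twa_72h, cvl = na_if_null(l$cv),
      lc6_raw = l$lc$h6[["raw"]], lc6_ip = l$lc$h6[["ip"]],
      lc24_raw = l$lc$h24[["raw"]], lc24_ip = l$lc$h24[["ip"]],
      lc72_raw = l$lc$h72[["raw"]], lc72_ip = l$lc$h72[["ip"]],
      abgl = if (is.null(r)) NA_real_ else na_if_null(r$ab),
      mbgl = if (is.null(r)) NA_real_ else r$mb,
      twagl = if (is.null(r)) NA_real_ else r$twa,
      twagl_72h = if (is.null(r)) NA_real_ else r$twa_72h,
      cvgl = if (is.null(r)) NA_real_ else na_if_null(r$cv),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
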