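#' Trajectory parameters for one marker
#'
#' Mean marker curve `m(t) = plateau + (baseline - plateau) *
#' exp(-decay_rate * t) + bump(t)`, where `bump(t)` is a Gaussian peak of
#' amplitude `second_peak_amp` centered at `second_peak_time` with width
#' (SD) `second_peak_width`. Survivor-shaped curves decline to a plateau;
#' non-survivor curves add the secondary peak (centered by default at
#' 132 h, i.e. ICU day 5.5) producing a biphasic pattern.
#'
#' @param baseline marker value at admission (marker units)
#' @param decay_rate exponential decay toward the plateau (1/h)
#' @param plateau asymptotic value (> 0)
#' @param second_peak_amp secondary-peak amplitude (>= 0; 0 disables it)
#' @param second_peak_time secondary-peak center (hours)
#' @param second_peak_width secondary-peak SD (hours)
#' @param noise_sd measurement noise SD (marker units)
#' @return a `trajectory_params` list
#' @export
trajectory_params <- function(baseline, decay_rate, plateau,
                              second_peak_amp = 0, second_peak_time = 132,
                              second_peak_width = 26, noise_sd = 0) {
  stopifnot(plateau > 0, baseline > 0, decay_rate >= 0,
            second_peak_amp >= 0, second_peak_width > 0, noise_sd >= 0)
  structure(list(baseline = baseline, decay_rate = decay_rate,
                 plateau = plateau, second_peak_amp = second_peak_amp,
                 second_peak_time = second_peak_time,
                 second_peak_width = second_peak_width,
                 noise_sd = noise_sd),
            class = "trajectory_params")
}

#' Evaluate the noise-free mean trajectory
#' @param params a [trajectory_params()]
#' @param t times (hours)
#' @return mean marker values at `t`
#' @export
trajectory_mean <- function(params, t) {
  params$plateau +
    (params$baseline - params$plateau) * exp(-params$decay_rate * t) +
    params$second_peak_amp *
      exp(-(t - params$second_peak_time)^2 / (2 * params$second_peak_width^2))
}

#' Closed-form time-weighted average of the mean trajectory
#'
#' Analytic integral of the exponential-plus-Gaussian mean curve over
#' `[0, t_end]`, divided by `t_end`. This is the "true" (noise-free,
#' continuous-time) TWA used as generating covariate and as ground truth.
#'
#' @param params a [trajectory_params()]
#' @param t_end upper limit (hours, > 0)
#' @return analytic TWA over `[0, t_end]`
#' @export
trajectory_twa <- function(params, t_end) {
  stopifnot(t_end > 0)
  d <- params$decay_rate
  exp_part <- if (d > 0) {
    (params$baseline - params$plateau) * (1 - exp(-d * t_end)) / d
  } else {
    (params$baseline - params$plateau) * t_end
  }
  w <- params$second_peak_width
  bump_part <- params$second_peak_amp * w * sqrt(2 * pi) *
    (pnorm((t_end - params$second_peak_time) / w) -
       pnorm(-params$second_peak_time / w))
  (params$plateau * t_end + exp_part + bump_part) / t_end
}

#' Simulation configuration
#'
#' @param n_patients cohort size (>= 2)
#' @param mortality_logit numeric `c(intercept, twal)`: log-odds of ICU
#'   death as a linear function of the patient's latent (noise-free,
#'   pre-peak) time-weighted average lactate over the first 240 h
#' @param sampling_rate mean blood-gas analyses per day (>= 4, matching
#'   the eligibility floor); sampling gaps are exponential with this mean
#'   rate, truncated at 6 h
#' @param admission_delay `c(min, max)` hours for the uniform first-sample
#'   delay
#' @param los_meanlog_surv,los_meanlog_nonsurv log-median ICU
#'   length-of-stay (hours) by group (non-survivors shorter)
#' @param los_sdlog log-SD of length of stay
#' @param los_range `c(min, max)` truncation of length of stay (hours)
#' @param seed RNG seed; fixed seed implies byte-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_patients = 200,
                       mortality_logit = c(intercept = -2.4, twal = 1.4),
                       sampling_rate = 6,
                       admission_delay = c(0.15, 0.6),
                       los_meanlog_surv = log(360),
                       los_meanlog_nonsurv = log(215),
                       los_sdlog = 0.55,
                       los_range = c(76, 1000),
                       seed = 1L) {
  stopifnot(n_patients >= 2, sampling_rate >= 4,
            length(mortality_logit) == 2, length(admission_delay) == 2,
            admission_delay[1] > 0, admission_delay[1] <= admission_delay[2],
            los_range[1] > 0, los_range[1] < los_range[2])
  structure(list(n_patients = as.integer(n_patients),
                 mortality_logit = mortality_logit,
                 sampling_rate = sampling_rate,
                 admission_delay = admission_delay,
                 los_meanlog_surv = los_meanlog_surv,
                 los_meanlog_nonsurv = los_meanlog_nonsurv,
                 los_sdlog = los_sdlog, los_range = los_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default group-level trajectory parameters
#'
#' Anchored to the qualitative group patterns of matched ICU cohorts:
#' survivor lactate declines over the first ~3 days and plateaus;
#' non-survivor lactate is biphasic with a secondary rise on days 4-8;
#' glucose declines with a smaller transient rise in non-survivors around
#' days 6-7; admission lactate differs little between groups while
#' plateau values do.
#'
#' @return nested list `[[group]][[marker]]` of [trajectory_params()],
#'   groups `survivor` / `nonsurvivor`, markers `glucose` / `lactate`
#' @export
default_trajectories <- function() {
  list(
    survivor = list(
      glucose = trajectory_params(baseline = 145, decay_rate = 0.035,
                                  plateau = 126, noise_sd = 16),
      lactate = trajectory_params(baseline = 1.9, decay_rate = 0.040,
                                  plateau = 0.80, noise_sd = 0.22)
    ),
    nonsurvivor = list(
      glucose = trajectory_params(baseline = 156, decay_rate = 0.035,
                                  plateau = 131, second_peak_amp = 16,
                                  second_peak_time = 150,
                                  second_peak_width = 22, noise_sd = 17),
      lactate = trajectory_params(baseline = 1.9, decay_rate = 0.035,
                                  plateau = 0.85, second_peak_amp = 0.40,
                                  second_peak_time = 132,
                                  second_peak_width = 26, noise_sd = 0.26)
    )
  )
}

sample_times <- function(los, config) {
  gap_mean <- 24 / config$sampling_rate
  t <- runif(1, config$admission_delay[1], config$admission_delay[2])
  n_guess <- max(20L, ceiling(2 * los / gap_mean))
  gaps <- pmin(rexp(n_guess, rate = 1 / gap_mean), 6)
  tt <- t + c(0, cumsum(gaps))
  while (tt[length(tt)] <= los) {
    gaps <- pmin(rexp(n_guess, rate = 1 / gap_mean), 6)
    tt <- c(tt, tt[length(tt)] + cumsum(gaps))
  }
  tt[tt <= los]
}

#' Simulate one patient's blood-gas series
#'
#' Draws irregular sampling times from a renewal process (exponential
#' gaps with mean `24 / sampling_rate` hours, truncated at 6 h; first
#' sample after a uniform admission delay) and observes glucose and
#' lactate jointly at each time with independent Gaussian noise. Values
#' are floored at a positivity epsilon (20 mg/dL glucose, 0.1 mmol/L
#' lactate).
#'
#' @param params list with elements `glucose` and `lactate`, each a
#'   [trajectory_params()]
#' @param icu_los observation span (hours)
#' @param config a [sim_config()] (sampling fields are used; the RNG
#'   stream is the caller's)
#' @return list with `series` (data.frame `t_hours`, `glucose_mgdl`,
#'   `lactate_mmoll`) and `icu_los`
#' @export
simulate_patient <- function(params, icu_los, config = sim_config()) {
  stopifnot(inherits(params$glucose, "trajectory_params"),
            inherits(params$lactate, "trajectory_params"))
  tt <- sample_times(icu_los, config)
  g <- trajectory_mean(params$glucose, tt) +
    rnorm(length(tt), 0, params$glucose$noise_sd)
  l <- trajectory_mean(params$lactate, tt) +
    rnorm(length(tt), 0, params$lactate$noise_sd)
  list(series = data.frame(t_hours = tt,
                           glucose_mgdl = pmax(g, 20),
                           lactate_mmoll = pmax(l, 0.1)),
       icu_los = icu_los)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

draw_covariates <- function(outcome) {
  n <- length(outcome)
  ns <- outcome == 1
  data.frame(
    age = round(rtrunc_norm(n, 58 + 10 * ns, 16, 18, 95)),
    sex = rbinom(n, 1, 0.68 + 0.05 * ns),
    bmi = round(rtrunc_norm(n, 25.3, 3.2, 16, 45), 1),
    gcs = pmin(pmax(round(rnorm(n, 9 - 1 * ns, 3.5)), 3), 15),
    isolated_tbi = rbinom(n, 1, 0.43 + 0.13 * ns),
    hypertension = rbinom(n, 1, 0.34 + 0.11 * ns),
    ckd = rbinom(n, 1, 0.04 + 0.10 * ns),
    saps2 = round(rtrunc_norm(n, 34 + 6 * ns, 8, 10, 80))
  )
}

#' Simulate a cohort with exported ground truth
#'
#' Per patient, group-level trajectory parameters receive multiplicative
#' log-normal jitter on baseline and plateau (patient heterogeneity). The
#' latent time-weighted average lactate (noise-free, secondary peak
#' excluded, first 240 h) determines ICU mortality through the logistic
#' model in `config$mortality_logit`; non-survivors then receive the
#' biphasic (secondary peak) lactate and glucose shapes and a shorter
#' length of stay. Covariates are drawn with outcome-dependent shifts
#' (older, higher SAPS II, lower GCS non-survivors) so that unmatched
#' groups are imbalanced, as matching methods assume.
#'
#' @param config a [sim_config()]; `config$seed` seeds the RNG so a fixed
#'   config reproduces the cohort byte-for-byte
#' @param trajectories nested parameter list as from
#'   [default_trajectories()]
#' @param jitter_sdlog log-SD of patient-level baseline/plateau jitter,
#'   `c(glucose, lactate)`
#' @param include_series generate measurement series (default `TRUE`;
#'   `FALSE` returns covariates and ground truth only, for large
#'   simulation studies that use the latent indices)
#' @return list with `cohort` (a `bg_cohort`), `truth` (data.frame with
#'   per-patient latent and realized true TWA lactate and generating
#'   parameters) and `config`
#' @export
simulate_cohort <- function(config = sim_config(),
                            trajectories = default_trajectories(),
                            jitter_sdlog = c(glucose = 0.06, lactate = 0.25),
                            include_series = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  jit_g <- exp(rnorm(n, 0, jitter_sdlog[["glucose"]]))
  jit_l <- exp(rnorm(n, 0, jitter_sdlog[["lactate"]]))

  base_lac <- trajectories$survivor$lactate
  twal_latent <- vapply(seq_len(n), function(i) {
    p <- base_lac
    p$baseline <- p$baseline * jit_l[i]
    p$plateau <- p$plateau * jit_l[i]
    trajectory_twa(p, 240)
  }, numeric(1))

  eta <- config$mortality_logit[[1]] + config$mortality_logit[[2]] * twal_latent
  outcome <- rbinom(n, 1, plogis(eta))
  if (n >= 20 && length(unique(outcome)) == 1L) {
    warning("degenerate simulation: all patients share one outcome; ",
            "consider adjusting mortality_logit")
  }

  meanlog <- ifelse(outcome == 1, config$los_meanlog_nonsurv,
                    config$los_meanlog_surv)
  los <- pmin(pmax(exp(rnorm(n, meanlog, config$los_sdlog)),
                   config$los_range[1]), config$los_range[2])

  covs <- draw_covariates(outcome)
  covariates <- cbind(data.frame(patient_id = ids, outcome = outcome,
                                 icu_los_hours = los,
                                 stringsAsFactors = FALSE),
                      covs)

  pat_params <- lapply(seq_len(n), function(i) {
    grp <- if (outcome[i] == 1) "nonsurvivor" else "survivor"
    pg <- trajectories[[grp]]$glucose
    pl <- trajectories[[grp]]$lactate
    pg$baseline <- pg$baseline * jit_g[i]
    pg$plateau <- pg$plateau * jit_g[i]
    pl$baseline <- pl$baseline * jit_l[i]
    pl$plateau <- pl$plateau * jit_l[i]
    list(glucose = pg, lactate = pl)
  })

  twal_true <- vapply(seq_len(n), function(i) {
    trajectory_twa(pat_params[[i]]$lactate, los[i])
  }, numeric(1))

  truth <- data.frame(patient_id = ids, outcome = outcome,
                      icu_los_hours = los,
                      twal_latent = twal_latent, twal_true = twal_true,
                      logit_intercept = config$mortality_logit[[1]],
                      logit_twal = config$mortality_logit[[2]],
                      stringsAsFactors = FALSE)

  if (include_series) {
    meas <- vector("list", n)
    for (i in seq_len(n)) {
      sim <- simulate_patient(pat_params[[i]], los[i], config)
      meas[[i]] <- cbind(data.frame(patient_id = ids[i],
                                    stringsAsFactors = FALSE),
                         sim$series)
    }
    measurements <- do.call(rbind, meas)
  } else {
    measurements <- data.frame(patient_id = character(0),
                               t_hours = numeric(0),
                               glucose_mgdl = numeric(0),
                               lactate_mmoll = numeric(0))
  }

  cohort <- bg_cohort(measurements, covariates,
                      meta = list(seed = config$seed,
                                  generator = "icumet::simulate_cohort"))
  list(cohort = cohort, truth = truth, config = config)
}
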