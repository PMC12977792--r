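# Small in-code fixtures and independent oracles shared across tests.

toy_measurements <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    t_hours = c(0.5, 6, 12, 1, 10),
    glucose_mgdl = c(140, 190, 120, 100, NA),
    lactate_mmoll = c(2.0, 1.5, 1.0, 1.2, 0.9),
    stringsAsFactors = FALSE)
}

toy_covariates <- function() {
  data.frame(
    patient_id = c("P1", "P2"),
    outcome = c(1, 0),
    icu_los_hours = c(100, 80),
    age = c(70, 45), sex = c(1, 0), bmi = c(25.1, 27.3),
    gcs = c(7, 12), isolated_tbi = c(1, 0), hypertension = c(1, 0),
    ckd = c(0, 0), saps2 = c(40, 30),
    stringsAsFactors = FALSE)
}

toy_cohort <- function() bg_cohort(toy_measurements(), toy_covariates())

# independent trapezoid oracle: piecewise-linear curve evaluated on a dense
# grid that includes the sample times (so the trapezoid sum is exact)
dense_twa_oracle <- function(t, v, lo, hi, step = 0.01) {
  lo <- max(lo, min(t)); hi <- min(hi, max(t))
  grid <- sort(unique(c(seq(lo, hi, by = step), hi, t[t >= lo & t <= hi])))
  y <- approx(t, v, xout = grid)$y
  if (length(grid) == 1L) return(y)
  sum(diff(grid) * (y[-length(y)] + y[-1]) / 2) / (hi - lo)
}

# exhaustive Mann-Whitney pair counting with half credit for ties
pair_count_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (x in cs) tot <- tot + sum(x > ct) + 0.5 * sum(x == ct)
  tot / (length(cs) * length(ct))
}

random_series <- function(n = NULL, t_max = 240) {
  if (is.null(n)) n <- sample(2:40, 1)
  gaps <- runif(n, 0.05, 6)
  t <- cumsum(gaps)
  t <- t * (t_max / max(t)) * runif(1, 0.3, 1)
  marker_series(t, runif(n, 50, 200), marker = "glucose")
}

# cohort of independent patients with one binary + one continuous covariate
# and planted confounding (covariates shift the outcome probability)
confounded_cohort <- function(n = 300, seed = 1) {
  sim <- simulate_cohort(sim_config(n_patients = n, seed = seed),
                         include_series = FALSE)
  sim$cohort
}
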