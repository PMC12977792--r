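test_that("ratio series pairs analytes at common timestamps only", {
  g <- marker_series(c(0, 1, 2), c(180, 150, 120), "glucose")
  l <- marker_series(c(1, 2, 4), c(1.0, 2.0, 1.5), "lactate")
  r <- ratio_series(g, l)
  expect_equal(r$t, c(1, 2))                       # intersection semantics
  expect_equal(r$value[1], (150 / 18) / 1.0)
  expect_equal(nrow(r), length(intersect(g$t, l$t)))

  r1 <- ratio_series(marker_series(1, 180, "glucose"),
                     marker_series(1, 1.0, "lactate"))
  expect_equal(r1$value, 10.0)                     # 180/18 = 10

  r2 <- ratio_series(marker_series(3, 140.4, "glucose"),
                     marker_series(3, 1.2, "lactate"))
  expect_equal(r2$value, 6.5)                      # (140.4/18)/1.2

  expect_error(ratio_series(marker_series(0, 100, "glucose"),
                            marker_series(1, 1, "lactate")),
               class = "icumet_empty_series_error")
})

test_that("admission value takes the earliest point inside the window", {
  expect_equal(admission_value(marker_series(c(0.5, 2), c(110, 120),
                                             "glucose")), 110)
  expect_true(is.na(admission_value(marker_series(6.5, 100, "glucose"))))
  expect_equal(admission_value(marker_series(6.0, 100, "glucose")), 100)
})

test_that("mean value is the unweighted arithmetic mean", {
  expect_equal(mean_value(marker_series(1, 100, "glucose")), 100)
  expect_equal(mean_value(marker_series(1:3, c(1, 2, 3), "lactate")), 2)
  set.seed(4)
  v <- runif(500, 60, 200)
  s <- marker_series(sort(runif(500, 0, 100)), v, "glucose")
  expect_equal(mean_value(s), sum(v) / 500, tolerance = 1e-14)
})

test_that("trapezoidal TWA matches hand and dense-resampling oracles", {
  # constant invariance
  s <- marker_series(c(0, 1.3, 7, 20), rep(100, 4), "glucose")
  expect_equal(time_weighted_average(s), 100)
  # single trapezoid mean
  expect_equal(time_weighted_average(
    marker_series(c(0, 2), c(1, 3), "lactate")), 2)
  # hand trapezoid: (0,1),(1,3),(3,3) -> (2 + 6)/3
  expect_equal(time_weighted_average(
    marker_series(c(0, 1, 3), c(1, 3, 3), "lactate")), 8 / 3)
  # window boundaries interpolated, denominator = covered span
  s2 <- marker_series(c(2, 4, 10), c(1, 3, 3), "lactate")
  expect_equal(time_weighted_average(s2, 0, 3),
               dense_twa_oracle(s2$t, s2$value, 0, 3), tolerance = 1e-9)
  expect_error(time_weighted_average(s2, 20, 30),
               class = "icumet_no_data_error")
})

test_that("TWA invariants: bounds, collinear insertion, unit rescaling", {
  set.seed(7)
  for (i in 1:25) {
    s <- random_series()
    twa <- time_weighted_average(s)
    expect_gte(twa, min(s$value))
    expect_lte(twa, max(s$value))
    # insert collinear midpoints: TWA unchanged
    tm <- (s$t[-1] + s$t[-nrow(s)]) / 2
    vm <- approx(s$t, s$value, xout = tm)$y
    o <- order(c(s$t, tm))
    s2 <- marker_series(c(s$t, tm)[o], c(s$value, vm)[o], "glucose")
    expect_equal(time_weighted_average(s2), twa, tolerance = 1e-10)
    # time-unit rescaling (hours -> minutes) leaves TWA unchanged
    s3 <- marker_series(s$t * 60, s$value, "glucose")
    expect_equal(time_weighted_average(s3), twa, tolerance = 1e-10)
  }
})

test_that("TWA equals the arithmetic mean on equally spaced symmetric series", {
  # endpoints get half weight under the trapezoid rule, so equality
  # holds when the (symmetric) endpoints equal the overall mean
  v <- c(5, 3, 9, 3, 5)
  s <- marker_series(seq(0, 8, by = 2), v, "lactate")
  expect_equal(time_weighted_average(s), mean(v))
})

test_that("interval TWA matches the dense-resampling oracle per window", {
  s <- marker_series(c(0, 10, 30, 48), rep(2.5, 4), "lactate")
  tw <- twa_by_interval(s, 24)
  expect_equal(tw$twa, c(2.5, 2.5))
  # partial trailing coverage and missing windows
  s2 <- marker_series(c(0, 12, 30), c(1, 2, 3), "lactate")
  tw2 <- twa_by_interval(s2, 24, t_max = 72)
  expect_equal(nrow(tw2), 3L)
  expect_false(any(is.na(tw2$twa[1:2])))
  expect_true(is.na(tw2$twa[3]))
  set.seed(12)
  for (i in 1:10) {
    s3 <- random_series(n = 30)
    tw3 <- twa_by_interval(s3, 24)
    for (k in seq_len(nrow(tw3))) {
      if (is.na(tw3$twa[k])) next
      expect_equal(tw3$twa[k],
                   dense_twa_oracle(s3$t, s3$value, tw3$t_start[k],
                                    tw3$t_end[k]),
                   tolerance = 1e-6)
    }
  }
})

test_that("CV uses the sample SD as a percentage of the mean", {
  expect_equal(coefficient_of_variation(
    marker_series(1:3, c(5, 5, 5), "glucose")), 0)
  expect_equal(coefficient_of_variation(
    marker_series(1:3, c(1, 2, 3), "glucose")), 50)
  set.seed(3)
  v <- runif(200, 1, 5)
  s <- marker_series(sort(runif(200)) * 100, v, "lactate")
  two_pass <- 100 * sqrt(sum((v - mean(v))^2) / 199) / mean(v)
  expect_equal(coefficient_of_variation(s), two_pass, tolerance = 1e-9)
  expect_error(coefficient_of_variation(marker_series(1, 2, "lactate")),
               class = "icumet_insufficient_data_error")
})

test_that("lactate clearance follows the raw/interpolated contracts", {
  s <- marker_series(c(0, 24), c(2, 1), "lactate")
  expect_equal(lactate_clearance(s, 24, "raw"), 50)
  expect_equal(lactate_clearance(s, 24, "interpolated"), 50)
  # interpolation between bracketing points: 2.0@20h, 1.0@28h -> 1.5@24h
  s2 <- marker_series(c(0, 20, 28), c(2, 2, 1), "lactate")
  expect_equal(lactate_clearance(s2, 24, "interpolated"), 25)
  # rising lactate gives negative clearance
  s3 <- marker_series(c(0, 70), c(1, 1.5), "lactate")
  expect_equal(lactate_clearance(s3, 72, "raw"), -50)
  # raw needs a second in-window point; interpolated needs a bracketing point
  s4 <- marker_series(c(0, 30), c(2, 1), "lactate")
  expect_true(is.na(lactate_clearance(s4, 24, "raw")))
  expect_true(is.na(lactate_clearance(marker_series(0, 2, "lactate"),
                                      24, "raw")))
  expect_true(is.na(lactate_clearance(s4, 72, "interpolated")))
  # a measurement exactly at the horizon makes raw and interpolated agree
  s5 <- marker_series(c(0, 10, 24), c(2, 1.4, 1.2), "lactate")
  expect_equal(lactate_clearance(s5, 24, "raw"),
               lactate_clearance(s5, 24, "interpolated"))
})

test_that("TUDR counts dysglycemic occupied periods", {
  cfg <- tudr_config()
  # all in range
  s <- marker_series(c(1, 7, 13), c(100, 120, 150), "glucose")
  expect_equal(tudr(s, 6, icu_los = 18), 0)
  # 4 periods, one empty, 1 of 3 occupied dysglycemic
  s2 <- marker_series(c(1, 7, 20), c(100, 250, 150), "glucose")
  expect_equal(tudr(s2, 6, icu_los = 24), 100 / 3)
  # any-excursion rule: one bad value taints the period
  s3 <- marker_series(c(1, 2, 3), c(100, 60, 120), "glucose")
  expect_equal(tudr(s3, 6, icu_los = 6), 100)
})

test_that("widening the TUDR target range never increases TUDR", {
  set.seed(21)
  for (i in 1:20) {
    s <- random_series(n = 25)
    los <- max(s$t) + runif(1, 0, 6)
    narrow <- tudr(s, 6, icu_los = los,
                   config = tudr_config(target_low = 90, target_high = 160))
    wide <- tudr(s, 6, icu_los = los,
                 config = tudr_config(target_low = 70, target_high = 180))
    expect_lte(wide, narrow)
  }
})

test_that("TUDR period selection picks the shortest adequately covered length", {
  make_co <- function(gap, los = 120, n_pat = 3) {
    meas <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      t <- seq(0.25, los - 0.5, by = gap)
      data.frame(patient_id = paste0("P", i), t_hours = t,
                 glucose_mgdl = 120, lactate_mmoll = 1.0)
    }))
    covs <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      cbind(toy_covariates()[1, -1], patient_id = paste0("P", i))
    }))
    covs$patient_id <- paste0("P", seq_len(n_pat))
    covs$icu_los_hours <- los
    covs$outcome <- c(1, rep(0, n_pat - 1))
    bg_cohort(meas, covs)
  }
  expect_equal(select_tudr_period(make_co(gap = 0.5)), 1)
  # 5-hourly sampling: 1-4 h candidates fail the 95% median coverage
  co5 <- make_co(gap = 5)
  brute <- vapply(c(1, 2, 3, 4, 6, 8, 12), function(p) {
    t <- seq(0.25, 119.5, by = 5)
    length(unique(floor(t / p))) / ceiling(120 / p)
  }, numeric(1))
  expect_equal(min(which(brute >= 0.95)), 5L)  # candidate index of 6 h
  expect_equal(select_tudr_period(co5), 6)
  # fallback: hopeless coverage returns the largest candidate with a warning
  meas1 <- data.frame(patient_id = "P1", t_hours = 1, glucose_mgdl = 120,
                      lactate_mmoll = 1)
  cov1 <- toy_covariates()[1, ]
  cov1$icu_los_hours <- 240
  co1 <- bg_cohort(meas1, cov1)
  expect_warning(p <- select_tudr_period(co1), "largest candidate")
  expect_equal(p, 12)
})

test_that("TUDR period shortens as sampling intensity increases", {
  set.seed(31)
  picks <- vapply(c(4, 8, 16), function(rate) {
    sim <- simulate_cohort(sim_config(n_patients = 25, seed = 100 + rate,
                                      sampling_rate = rate))
    select_tudr_period(sim$cohort)
  }, numeric(1))
  expect_true(all(diff(picks) <= 0))
})

test_that("per-patient index sets agree with the standalone operations", {
  # constant markers: all central indices collapse onto the constants
  meas <- data.frame(patient_id = "P1", t_hours = c(0.5, 10, 40, 90),
                     glucose_mgdl = 100, lactate_mmoll = 1.0)
  cov <- toy_covariates()[1, ]
  rec <- patient_record(bg_cohort(meas, cov), "P1")
  s <- compute_index_sets(rec, tudr_period = 6)
  expect_equal(s$glucose$ab, 100)
  expect_equal(s$glucose$mb, 100)
  expect_equal(s$glucose$twa, 100)
  expect_equal(s$lactate$twa, 1.0)
  expect_equal(s$ratio$twa, 100 / 18, tolerance = 1e-12)
  expect_equal(s$glucose$cv, 0)
  expect_equal(s$glucose$tudr, 0)

  # sampling ending at 48 h: 72h-TWA truncates to the covered span
  meas2 <- meas; meas2$t_hours <- c(0.5, 10, 30, 48)
  rec2 <- patient_record(bg_cohort(meas2, cov), "P1")
  s2 <- compute_index_sets(rec2, tudr_period = 6)
  expect_equal(s2$glucose$twa_72h, s2$glucose$twa)

  # simulated patient: every cell equals its standalone-op oracle
  sim <- simulate_cohort(sim_config(n_patients = 5, seed = 9))
  idx <- cohort_index_table(sim$cohort, tudr_period = 6)
  rec3 <- patient_record(sim$cohort, idx$patient_id[1])
  g <- marker_series(rec3$series$t_hours, rec3$series$glucose_mgdl,
                     "glucose")
  l <- marker_series(rec3$series$t_hours, rec3$series$lactate_mmoll,
                     "lactate")
  r <- ratio_series(g, l)
  expect_equal(idx$abg[1], admission_value(g))
  expect_equal(idx$mbg[1], mean_value(g))
  expect_equal(idx$twag[1], time_weighted_average(g))
  expect_equal(idx$twag_72h[1], time_weighted_average(g, 0, 72))
  expect_equal(idx$cvg[1], coefficient_of_variation(g))
  expect_equal(idx$tudr[1], tudr(g, 6, icu_los = rec3$icu_los))
  expect_equal(idx$twal[1], time_weighted_average(l))
  expect_equal(idx$lc24_ip[1], lactate_clearance(l, 24, "interpolated"))
  expect_equal(idx$lc72_raw[1], lactate_clearance(l, 72, "raw"))
  expect_equal(idx$twagl[1], time_weighted_average(r))
  expect_equal(idx$cvgl[1], coefficient_of_variation(r))
})
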