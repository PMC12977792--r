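#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline in the Harrell truncated-power
#' parameterization: with knots `k_1 < ... < k_K` the basis has `K - 1`
#' columns — the linear term plus `K - 2` cubic terms
#' \deqn{X_j(x) = [(x-k_j)_+^3 - (x-k_{K-1})_+^3 (k_K-k_j)/(k_K-k_{K-1})
#'   + (x-k_K)_+^3 (k_{K-1}-k_j)/(k_K-k_{K-1})] / (k_K-k_1)^2,}
#' which is continuous with continuous first and second derivatives at
#' the knots and exactly linear beyond the boundary knots. Six knots give
#' the standard 5-df time basis.
#'
#' @param times observed times (hours) used for quantile knot placement
#' @param n_knots number of knots (>= 3; default 6, i.e. 5 df)
#' @param knots explicit knot locations (overrides quantile placement)
#' @return an `rcs_basis`: list with `knots` and `df`; evaluate with
#'   [rcs_eval()]
#' @export
rcs_basis <- function(times, n_knots = 6, knots = NULL) {
  if (is.null(knots)) {
    stopifnot(n_knots >= 3)
    if (length(unique(times)) < n_knots) {
      stop_icumet("format", "need at least ", n_knots, " distinct times ",
                  "for ", n_knots, " knots")
    }
    probs <- switch(as.character(n_knots),
                    "3" = c(0.10, 0.50, 0.90),
                    "4" = c(0.05, 0.35, 0.65, 0.95),
                    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
                    "7" = c(0.025, 0.1833, 0.3417, 0.5, 0.6583,
                            0.8167, 0.975),
                    seq(0.05, 0.95, length.out = n_knots))
    knots <- as.numeric(quantile(times, probs, type = 7, names = FALSE))
  }
  if (is.unsorted(knots, strictly = TRUE)) {
    stop_icumet("format", "knots must be strictly increasing (ties arise ",
                "when too few distinct times are available)")
  }
  structure(list(knots = knots, df = length(knots) - 1L),
            class = "rcs_basis")
}

#' Evaluate a restricted cubic spline basis
#'
#' @param basis an [rcs_basis()]
#' @param t evaluation times
#' @return numeric matrix `length(t) x basis$df` with columns `rcs1`
#'   (linear term) .. `rcs<df>`
#' @export
rcs_eval <- function(basis, t) {
  stopifnot(inherits(basis, "rcs_basis"))
  k <- basis$knots
  K <- length(k)
  pos3 <- function(x) pmax(x, 0)^3
  scale2 <- (k[K] - k[1])^2
  out <- matrix(0, nrow = length(t), ncol = basis$df)
  out[, 1] <- t
  for (j in seq_len(K - 2)) {
    out[, j + 1] <- (pos3(t - k[j]) -
                       pos3(t - k[K - 1]) * (k[K] - k[j]) / (k[K] - k[K - 1]) +
                       pos3(t - k[K]) * (k[K - 1] - k[j]) / (k[K] - k[K - 1])
                     ) / scale2
  }
  colnames(out) <- paste0("rcs", seq_len(basis$df))
  out
}

#' Fit the trajectory mixed model
#'
#' Linear mixed-effects model for interval-TWA marker values: fixed
#' effects for group (non-survivor), restricted-cubic-spline time and
#' their interaction; a random intercept per patient; AR(1) correlation
#' over consecutive intervals within patient; estimation by REML (or ML
#' for likelihood-ratio comparisons of knot counts).
#'
#' @param data long data.frame with columns `patient_id`, `group` (0/1),
#'   `interval` (0-based bin index) and `value` (bin TWA); missing bins
#'   are simply absent rows (unbalanced panels are handled, nothing is
#'   imputed)
#' @param interval_hours bin width in hours (24 for daily bins, 6 for the
#'   visualization scale)
#' @param n_knots spline knots (default 6, i.e. 5 df)
#' @param method `"REML"` (default) or `"ML"`
#' @return a `trajectory_fit`: list with the `nlme::lme` `model`, the
#'   `basis`, variance components (`sigma_intercept`, `ar1_rho`,
#'   `sigma_resid`), `logLik`, `AIC`, Wald tests `group_test`
#'   (group main + interaction) and `interaction_test` (group x time
#'   interaction only), and the modeling `data`
#' @export
fit_trajectory_model <- function(data, interval_hours = 24, n_knots = 6,
                                 method = c("REML", "ML")) {
  method <- match.arg(method)
  req <- c("patient_id", "group", "interval", "value")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L) {
    stop_icumet("format", "trajectory data lacks column(s): ",
                paste(miss, collapse = ", "))
  }
  data <- data[!is.na(data$value), , drop = FALSE]
  if (!all(data$group %in% c(0, 1))) {
    stop_icumet("format", "group must be 0 (survivor) / 1 (non-survivor)")
  }
  if (length(unique(data$patient_id[data$group == 1])) < 2L ||
      length(unique(data$patient_id[data$group == 0])) < 2L) {
    stop_icumet("insufficient_data", "need >= 2 patients per group")
  }
  data$t_hours <- (data$interval + 0.5) * interval_hours
  basis <- rcs_basis(data$t_hours, n_knots = n_knots)
  B <- rcs_eval(basis, data$t_hours)
  dd <- cbind(data, B)
  dd$patient_id <- factor(dd$patient_id)
  dd <- dd[order(dd$patient_id, dd$interval), , drop = FALSE]
  spline_terms <- paste(colnames(B), collapse = " + ")
  form <- as.formula(paste("value ~ group * (", spline_terms, ")"))
  model <- tryCatch(
    nlme::lme(form, random = ~ 1 | patient_id,
              correlation = nlme::corAR1(form = ~ interval | patient_id),
              data = dd, method = method,
              control = nlme::lmeControl(msMaxIter = 200,
                                         returnObject = FALSE)),
    error = function(e) {
      stop_icumet("fit", "trajectory model did not converge: ",
                  conditionMessage(e))
    })
  vc <- nlme::VarCorr(model)
  rho <- coef(model$modelStruct$corStruct, unconstrained = FALSE)[[1]]
  fe <- nlme::fixef(model)
  V <- vcov(model)
  wald <- function(idx) {
    b <- fe[idx]
    W <- as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    list(statistic = W, df = length(idx),
         p = pchisq(W, df = length(idx), lower.tail = FALSE))
  }
  inter_idx <- grep("^group:", names(fe))
  group_idx <- c(which(names(fe) == "group"), inter_idx)
  structure(list(model = model, basis = basis,
                 interval_hours = interval_hours,
                 fixed = fe, vcov_fixed = V,
                 sigma_intercept = as.numeric(vc["(Intercept)", "StdDev"]),
                 ar1_rho = as.numeric(rho),
                 sigma_resid = model$sigma,
                 logLik = as.numeric(logLik(model)),
                 AIC = AIC(model),
                 converged = TRUE,
                 group_test = wald(group_idx),
                 interaction_test = wald(inter_idx),
                 data = dd),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("<trajectory_fit> RCS(", x$basis$df, " df) mixed model, ",
      nrow(x$data), " obs, ",
      nlevels(x$data$patient_id), " patients\n", sep = "")
  cat(sprintf("  random intercept SD %.3f | AR(1) rho %.3f | resid SD %.3f\n",
              x$sigma_intercept, x$ar1_rho, x$sigma_resid))
  cat(sprintf("  group x time Wald chi2(%d) = %.2f, p = %.4g\n",
              x$interaction_test$df, x$interaction_test$statistic,
              x$interaction_test$p))
  invisible(x)
}

emm_row <- function(fit, group, t) {
  B <- rcs_eval(fit$basis, t)
  x <- c(1, group, as.numeric(B), group * as.numeric(B))
  names(x) <- names(fit$fixed)
  x
}

#' Estimated marginal means and Bonferroni daily contrasts
#'
#' Model-based group means at the midpoint of each ICU day, with 95%
#' confidence intervals, and the per-day non-survivor minus survivor
#' contrast with raw and Bonferroni-adjusted p values (adjusted over the
#' number of days tested).
#'
#' @param fit a `trajectory_fit`
#' @param days ICU days to evaluate (default 1:10)
#' @param conf_level confidence level (default 0.95)
#' @return list with `emm` (data.frame `day`, `group`, `emm`, `lower`,
#'   `upper`) and `contrasts` (data.frame `day`, `estimate`, `se`, `z`,
#'   `p_raw`, `p_adj`)
#' @export
emm_daily_contrasts <- function(fit, days = 1:10, conf_level = 0.95) {
  stopifnot(inherits(fit, "trajectory_fit"))
  t_mid <- (days - 0.5) * 24
  t_max <- max(fit$data$t_hours)
  if (any(t_mid > t_max)) {
    warning("day(s) ", paste(days[t_mid > t_max], collapse = ", "),
            " lie beyond the modeled support (", round(t_max, 1),
            " h); estimates there are extrapolations")
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  rows <- list(); ctr <- list()
  for (i in seq_along(days)) {
    x0 <- emm_row(fit, 0, t_mid[i])
    x1 <- emm_row(fit, 1, t_mid[i])
    for (g in 0:1) {
      x <- if (g == 0) x0 else x1
      est <- sum(x * fit$fixed)
      se <- sqrt(as.numeric(t(x) %*% fit$vcov_fixed %*% x))
      rows[[length(rows) + 1L]] <- data.frame(
        day = days[i], group = g, emm = est,
        lower = est - zq * se, upper = est + zq * se)
    }
    dx <- x1 - x0
    est <- sum(dx * fit$fixed)
    se <- sqrt(as.numeric(t(dx) %*% fit$vcov_fixed %*% dx))
    z <- est / se
    p <- 2 * pnorm(-abs(z))
    ctr[[i]] <- data.frame(day = days[i], estimate = est, se = se, z = z,
                           p_raw = p, p_adj = min(1, p * length(days)))
  }
  list(emm = do.call(rbind, rows), contrasts = do.call(rbind, ctr))
}

#' Interval-TWA long table for the trajectory model
#'
#' Builds the model input: per patient, the TWA of one marker in
#' consecutive fixed-width bins over the first `n_days` ICU days.
#'
#' @param cohort a `bg_cohort`
#' @param marker `"glucose"`, `"lactate"` or `"ratio"`
#' @param interval_hours bin width (24 for the primary analysis, 6 for
#'   spline visualization)
#' @param n_days span in ICU days (default 10)
#' @return data.frame `patient_id`, `group`, `interval`, `value` (bins
#'   without coverage are omitted)
#' @export
interval_twa_table <- function(cohort, marker = c("lactate", "glucose",
                                                  "ratio"),
                               interval_hours = 24, n_days = 10) {
  stopifnot(inherits(cohort, "bg_cohort"))
  marker <- match.arg(marker)
  t_max <- n_days * 24
  rows <- lapply(cohort$covariates$patient_id, function(id) {
    rec <- patient_record(cohort, id)
    ser <- switch(marker,
                  ratio = {
                    g <- marker_from_record(rec, "glucose")
                    l <- marker_from_record(rec, "lactate")
                    if (is.null(g) || is.null(l)) NULL else
                      tryCatch(ratio_series(g, l),
                               icumet_empty_series_error = function(e) NULL)
                  },
                  marker_from_record(rec, marker))
    if (is.null(ser)) return(NULL)
    span <- min(t_max, rec$icu_los)
    tw <- twa_by_interval(ser, interval_hours, t_max = span)
    tw <- tw[!is.na(tw$twa), , drop = FALSE]
    if (nrow(tw) == 0L) return(NULL)
    data.frame(patient_id = id, group = rec$outcome, interval = tw$interval,
               value = tw$twa, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
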