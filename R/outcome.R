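#' @importFrom survival clogit strata coxph Surv
NULL

# classical variance inflation factors of the fixed design:
# VIF_j = 1/(1 - R2_j) of column j regressed on the others,
# i.e. the diagonal of the inverse correlation matrix
design_vif <- function(model) {
  X <- model.matrix(model)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2L) return(NULL)
  v <- diag(solve(cor(X)))
  names(v) <- colnames(X)
  v
}

#' Two-group comparison
#'
#' Continuous variables: two-tailed Mann-Whitney U test (tie-corrected).
#' Categorical variables: Fisher's exact test on the 2 x k table.
#'
#' @param values variable values
#' @param group binary group indicator (1 = non-survivor)
#' @param type `"continuous"` or `"categorical"`
#' @return list with `type`, `statistic` (U for continuous, odds ratio
#'   for 2x2 categorical), `p`, and group summaries (`median`/IQR for
#'   continuous, counts for categorical)
#' @export
group_compare <- function(values, group,
                          type = c("continuous", "categorical")) {
  type <- match.arg(type)
  stopifnot(length(values) == length(group), all(group %in% c(0, 1)))
  keep <- !is.na(values)
  values <- values[keep]; group <- group[keep]
  if (sum(group == 1) == 0L || sum(group == 0) == 0L) {
    stop_icumet("format", "both groups must be non-empty")
  }
  if (type == "continuous") {
    wt <- suppressWarnings(
      wilcox.test(values[group == 1], values[group == 0], exact = FALSE,
                  correct = TRUE))
    q <- function(g) quantile(values[group == g], c(0.5, 0.25, 0.75),
                              names = FALSE)
    s1 <- q(1); s0 <- q(0)
    list(type = type, statistic = unname(wt$statistic), p = wt$p.value,
         summary = data.frame(group = c(0, 1),
                              median = c(s0[1], s1[1]),
                              q25 = c(s0[2], s1[2]),
                              q75 = c(s0[3], s1[3])))
  } else {
    tab <- table(factor(group, levels = c(0, 1)), values)
    ft <- fisher.test(tab)
    list(type = type,
         statistic = if (!is.null(ft$estimate)) unname(ft$estimate)
                     else NA_real_,
         p = ft$p.value, summary = tab)
  }
}

#' Spearman collinearity screen
#'
#' Pairwise Spearman rank correlations among candidate indices; pairs
#' with `|rho|` above the threshold are flagged as collinear. Within a
#' flagged pair the time-weighted member is preferred; when both members
#' are time-weighted (e.g. TWA lactate and TWA glucose-lactate ratio)
#' both are retained but must be routed to separate model families.
#'
#' @param indices data.frame of index columns (complete rows used)
#' @param threshold collinearity threshold on `|rho|` (default 0.50)
#' @param time_weighted names of time-weighted columns (prefix `twa` by
#'   default)
#' @return list with `rho` (correlation matrix), `flagged` (data.frame
#'   `var1`, `var2`, `rho`, `separate_families`), `retained` (character),
#'   `degenerate` (constant columns, excluded)
#' @export
spearman_screen <- function(indices, threshold = 0.50,
                            time_weighted = NULL) {
  indices <- as.data.frame(indices)
  indices <- indices[, vapply(indices, is.numeric, logical(1)), drop = FALSE]
  cc <- indices[stats::complete.cases(indices), , drop = FALSE]
  if (nrow(cc) < 3L) {
    stop_icumet("insufficient_data", "need >= 3 complete rows")
  }
  degenerate <- names(cc)[vapply(cc, function(x) var(x) == 0, logical(1))]
  if (length(degenerate) > 0L) {
    warning("constant column(s) excluded from the screen: ",
            paste(degenerate, collapse = ", "))
    cc <- cc[, setdiff(names(cc), degenerate), drop = FALSE]
  }
  if (is.null(time_weighted)) {
    time_weighted <- grep("^twa", names(cc), value = TRUE)
  }
  rho <- cor(cc, method = "spearman")
  flagged <- list()
  vars <- colnames(rho)
  for (i in seq_len(ncol(rho) - 1L)) {
    for (j in seq((i + 1L), ncol(rho))) {
      if (abs(rho[i, j]) > threshold) {
        both_tw <- vars[i] %in% time_weighted && vars[j] %in% time_weighted
        flagged[[length(flagged) + 1L]] <- data.frame(
          var1 = vars[i], var2 = vars[j], rho = rho[i, j],
          separate_families = both_tw, stringsAsFactors = FALSE)
      }
    }
  }
  flagged_df <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(var1 = character(0), var2 = character(0), rho = numeric(0),
               separate_families = logical(0))
  dropped <- character(0)
  for (k in seq_len(nrow(flagged_df))) {
    v1 <- flagged_df$var1[k]; v2 <- flagged_df$var2[k]
    if (flagged_df$separate_families[k]) next
    tw1 <- v1 %in% time_weighted; tw2 <- v2 %in% time_weighted
    if (tw1 && !tw2) dropped <- union(dropped, v2)
    if (tw2 && !tw1) dropped <- union(dropped, v1)
    # neither time-weighted: keep both, flag only
  }
  list(rho = rho, flagged = flagged_df,
       retained = setdiff(vars, dropped), degenerate = degenerate)
}

#' Logistic regression with selectable variance estimator
#'
#' Maximum-likelihood logistic regression of a binary outcome on named
#' predictors, reporting odds ratios with Wald 95% confidence intervals,
#' z-scores and p values. Three variance flavours:
#' \describe{
#'   \item{`classical`}{the usual inverse-information Wald covariance.}
#'   \item{`cluster_robust`}{sandwich covariance with HC0 meat clustered
#'     on match sets and a finite-cluster correction `G/(G-1)`; with
#'     singleton clusters this equals the heteroskedasticity-robust
#'     sandwich.}
#'   \item{`conditional`}{conditional logistic regression maximizing the
#'     stratified likelihood per match set (no intercept).}
#' }
#' Variance inflation factors are reported for multivariable fits.
#'
#' @param data data.frame with the outcome and predictor columns
#'   (complete cases used; incomplete rows are dropped with a message)
#' @param outcome name of the binary outcome column
#' @param predictors character vector of predictor columns
#' @param variance `"classical"`, `"cluster_robust"` or `"conditional"`
#' @param cluster name of the cluster/stratum column (required for
#'   `cluster_robust` and `conditional`)
#' @param conf_level confidence level (default 0.95)
#' @return a `logistic_fit`: list with `coef` (data.frame `term`,
#'   `estimate`, `se`, `z`, `p`, `or`, `or_lower`, `or_upper`),
#'   `variance`, `vif` (named vector or `NULL`), `n`, `model`
#' @export
fit_logistic <- function(data, outcome = "outcome", predictors,
                         variance = c("classical", "cluster_robust",
                                      "conditional"),
                         cluster = NULL, conf_level = 0.95) {
  variance <- match.arg(variance)
  stopifnot(length(predictors) >= 1)
  need <- c(outcome, predictors,
            if (variance != "classical") cluster)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop_icumet("format", "column(s) absent: ", paste(miss, collapse = ", "))
  }
  if (variance != "classical" && is.null(cluster)) {
    stop_icumet("config", variance, " variance requires a cluster column")
  }
  dat <- data[, need, drop = FALSE]
  keep <- stats::complete.cases(dat)
  if (any(!keep)) {
    message("fit_logistic: dropped ", sum(!keep), " incomplete row(s)")
    dat <- dat[keep, , drop = FALSE]
  }
  if (!all(dat[[outcome]] %in% c(0, 1))) {
    stop_icumet("format", "outcome must be binary 0/1")
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)

  if (variance == "conditional") {
    form <- as.formula(paste(outcome, "~",
                             paste(predictors, collapse = " + "),
                             "+ strata(", cluster, ")"),
                       env = asNamespace("icumet"))
    model <- survival::clogit(form, data = dat)
    b <- coef(model)
    V <- vcov(model)
    vif_tab <- NULL
  } else {
    form <- as.formula(paste(outcome, "~",
                             paste(predictors, collapse = " + ")))
    model <- glm(form, data = dat, family = binomial())
    if (!model$converged) {
      stop_icumet("fit", "logistic fit did not converge")
    }
    p_hat <- fitted(model)
    if (any(p_hat < 1e-10) || any(p_hat > 1 - 1e-10)) {
      stop_icumet("fit", "(quasi-)separation: fitted probabilities of 0 or 1")
    }
    qr_r <- qr(model.matrix(model))
    if (qr_r$rank < ncol(model.matrix(model))) {
      bad <- colnames(model.matrix(model))[
        qr_r$pivot[seq(qr_r$rank + 1L, ncol(model.matrix(model)))]]
      stop_icumet("fit", "singular design; collinear column(s): ",
                  paste(bad, collapse = ", "))
    }
    b <- coef(model)
    V <- if (variance == "cluster_robust") {
      sandwich::vcovCL(model, cluster = dat[[cluster]], type = "HC0",
                       cadjust = TRUE)
    } else {
      vcov(model)
    }
    vif_tab <- if (length(predictors) >= 2L) design_vif(model) else NULL
  }
  se <- sqrt(diag(V))
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  coef_tab <- data.frame(term = names(b), estimate = unname(b),
                         se = unname(se), z = unname(z), p = unname(p),
                         or = exp(unname(b)),
                         or_lower = exp(unname(b - zq * se)),
                         or_upper = exp(unname(b + zq * se)),
                         stringsAsFactors = FALSE)
  rownames(coef_tab) <- NULL
  structure(list(coef = coef_tab, variance = variance, vif = vif_tab,
                 n = nrow(dat), vcov = V, model = model),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, variance = %s\n", x$n, x$variance))
  tab <- x$coef
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  if (!is.null(x$vif)) {
    cat("VIF:", paste(names(x$vif), signif(x$vif, 3), sep = "=",
                      collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC via the Mann-Whitney identity (ties receive half credit); the
#' variance and confidence interval come from DeLong's structural
#' components. Scores are oriented so that higher values predict
#' non-survival; an AUC below 0.5 (as for ratio indices, which protect)
#' is reported in that natural direction and flagged, never silently
#' inverted.
#'
#' @param scores numeric predictor values
#' @param labels binary outcome (1 = non-survivor)
#' @param conf_level confidence level (default 0.95)
#' @return a `roc_result`: list with `auc`, `ci` (clipped to \[0, 1\]),
#'   `se`, `inverse_direction` flag, `n_cases`, `n_controls`, and the
#'   underlying `pROC::roc` object
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L) {
    stop_icumet("format", "both outcome classes must be present")
  }
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                                method = "delong"))
  auc <- as.numeric(pROC::auc(r))
  se <- (ci[3] - ci[1]) / (2 * qnorm(1 - (1 - conf_level) / 2))
  structure(list(auc = auc, ci = pmin(pmax(c(ci[1], ci[3]), 0), 1),
                 se = se, inverse_direction = auc < 0.5,
                 n_cases = sum(labels == 1), n_controls = sum(labels == 0),
                 roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f [%.3f-%.3f] (%d cases / %d controls)%s\n",
              x$auc, x$ci[1], x$ci[2], x$n_cases, x$n_controls,
              if (x$inverse_direction) " [higher score predicts survival]"
              else ""))
  invisible(x)
}

#' Paired DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two predictors measured on the same subjects with
#' the same outcome labels, using the paired DeLong variance of the AUC
#' difference.
#'
#' @param scores_a,scores_b the two score vectors (same subjects)
#' @param labels binary outcome (1 = non-survivor)
#' @return list with `delta_auc` (`auc_a - auc_b`), `auc_a`, `auc_b`,
#'   `z`, `p` (two-tailed)
#' @export
paired_delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop_icumet("format", "scores_a, scores_b and labels must have equal ",
                "length (same subjects)")
  }
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  ra <- pROC::roc(labels[keep], scores_a[keep], levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels[keep], scores_b[keep], levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(delta_auc = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
       auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       z = unname(tst$statistic), p = tst$p.value)
}

#' Run the full discrimination/regression analysis grid
#'
#' Executes, on a per-patient index table joined with match-set
#' assignments: a univariable logistic screen over the indices; the four
#' multivariable models (glucose + lactate family with admission glucose,
#' TWA glucose and TWA lactate vs. the ratio family with TWA
#' glucose-lactate ratio, each over the first 72 h and the full stay,
#' always adjusted for sex and SAPS II); conditional and classical
#' sensitivity refits of the full-stay models; an ROC table over all
#' indices; and paired DeLong comparisons among indices significant in
#' the multivariable models. Group comparisons of every index are
#' included for descriptive tables.
#'
#' @param indices index table from [cohort_index_table()]
#' @param matched a `matched_cohort` (or `NULL` for an unmatched analysis
#'   with classical variance, flagged in the report)
#' @param covariate_data covariate table providing the adjustment
#'   variables (defaults to the matched cohort's covariates)
#' @param adjust covariates always included in multivariable models
#' @param alpha significance level for the univariable screen
#' @return an `analysis_report` list with elements `group_tables`,
#'   `univariable`, `multivariable`, `sensitivity`, `roc`, `delong`,
#'   `notes`
#' @export
run_model_suite <- function(indices, matched = NULL, covariate_data = NULL,
                            adjust = c("sex", "saps2"), alpha = 0.05) {
  notes <- character(0)
  if (is.null(covariate_data)) {
    if (is.null(matched)) {
      stop_icumet("config",
                  "covariate_data is required when matched is NULL")
    }
    covariate_data <- matched$cohort$covariates
  }
  dat <- merge(indices, covariate_data[, c("patient_id", adjust),
                                       drop = FALSE], by = "patient_id")
  if (!is.null(matched)) {
    sets <- matched$sets[, c("patient_id", "set_id")]
    dat <- merge(dat, sets, by = "patient_id")
    variance_main <- "cluster_robust"
    cluster <- "set_id"
  } else {
    dat$set_id <- seq_len(nrow(dat))
    variance_main <- "classical"
    cluster <- NULL
    notes <- c(notes, paste("no matched cohort supplied: analysis run",
                            "unmatched with classical variance"))
  }

  index_cols <- intersect(
    c("abg", "mbg", "twag", "twag_72h", "cvg", "tudr",
      "abl", "mbl", "twal", "twal_72h", "cvl",
      "lc6_raw", "lc6_ip", "lc24_raw", "lc24_ip", "lc72_raw", "lc72_ip",
      "abgl", "mbgl", "twagl", "twagl_72h", "cvgl"),
    names(dat))

  group_tables <- lapply(setNames(index_cols, index_cols), function(v) {
    tryCatch(group_compare(dat[[v]], dat$outcome, "continuous"),
             icumet_error = function(e) NULL)
  })

  uni <- lapply(setNames(index_cols, index_cols), function(v) {
    tryCatch(fit_logistic(dat, predictors = v, variance = "classical"),
             icumet_error = function(e) NULL)
  })
  uni_tab <- do.call(rbind, lapply(index_cols, function(v) {
    f <- uni[[v]]
    if (is.null(f)) return(NULL)
    row <- f$coef[f$coef$term == v, , drop = FALSE]
    cbind(data.frame(index = v, stringsAsFactors = FALSE), row[, -1])
  }))
  if (!is.null(uni_tab)) {
    uni_tab$significant <- uni_tab$p < alpha
  }

  families <- list(
    glucose_lactate_full = c("abg", "twag", "twal"),
    glucose_lactate_72h = c("abg", "twag", "twal_72h"),
    ratio_full = "twagl",
    ratio_72h = "twagl_72h")
  multi <- lapply(families, function(preds) {
    preds <- intersect(c(preds, adjust), names(dat))
    tryCatch(fit_logistic(dat, predictors = preds,
                          variance = variance_main, cluster = cluster),
             icumet_error = function(e) NULL)
  })

  sensitivity <- list()
  if (!is.null(matched)) {
    for (fam in c("glucose_lactate_full", "ratio_full")) {
      preds <- intersect(c(families[[fam]], adjust), names(dat))
      sensitivity[[paste0(fam, "_conditional")]] <-
        tryCatch(fit_logistic(dat, predictors = preds,
                              variance = "conditional", cluster = "set_id"),
                 icumet_error = function(e) NULL)
      sensitivity[[paste0(fam, "_classical")]] <-
        tryCatch(fit_logistic(dat, predictors = preds,
                              variance = "classical"),
                 icumet_error = function(e) NULL)
    }
  }

  roc_tab <- do.call(rbind, lapply(index_cols, function(v) {
    r <- tryCatch(roc_auc(dat[[v]], dat$outcome),
                  icumet_error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(index = v, auc = r$auc, ci_lower = r$ci[1],
               ci_upper = r$ci[2],
               predicts_survival = r$inverse_direction,
               stringsAsFactors = FALSE)
  }))

  sig_idx <- character(0)
  for (fam in names(multi)) {
    f <- multi[[fam]]
    if (is.null(f)) next
    fam_idx <- intersect(families[[fam]], f$coef$term)
    sig <- f$coef$term[f$coef$term %in% fam_idx & f$coef$p < alpha]
    sig_idx <- union(sig_idx, sig)
  }
  delong <- list()
  if (length(sig_idx) >= 2L) {
    pairs <- utils::combn(sort(sig_idx), 2, simplify = FALSE)
    delong <- lapply(pairs, function(pr) {
      c(list(index_a = pr[1], index_b = pr[2]),
        paired_delong_test(dat[[pr[1]]], dat[[pr[2]]], dat$outcome))
    })
  }

  structure(list(group_tables = group_tables, univariable = uni_tab,
                 multivariable = multi, sensitivity = sensitivity,
                 roc = roc_tab, delong = delong,
                 significant_indices = sig_idx,
                 n = nrow(dat), notes = notes),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> n = %d\n", x$n))
  if (!is.null(x$univariable)) {
    cat(sprintf("  univariable screen: %d/%d indices significant\n",
                sum(x$univariable$significant), nrow(x$univariable)))
  }
  cat("  multivariable-significant indices:",
      if (length(x$significant_indices))
        paste(x$significant_indices, collapse = ", ") else "(none)", "\n")
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
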