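#' Derive (time, event) pairs with optional transplant censoring
#'
#' Overall survival runs from diagnosis to death or last follow-up. When
#' `censor_at_hsct` is `TRUE` (the primary analysis), patients who underwent
#' hematopoietic stem-cell transplantation are censored at the transplant
#' time; with `FALSE` their full follow-up and death status are used (the
#' transplant sub-analyses).
#'
#' @param cohort an `mn_cohort`.
#' @param censor_at_hsct censor at transplant time?
#' @return data.frame with `patient_id`, `time`, `event` (1 death, 0
#'   censored).
#' @export
prepare_survival <- function(cohort, censor_at_hsct = TRUE) {
  stopifnot(inherits(cohort, "mn_cohort"))
  cl <- cohort$clinical
  if (any(cl$os_years < 0)) stop("negative survival time", call. = FALSE)
  time <- cl$os_years
  event <- as.integer(cl$death)
  if (censor_at_hsct) {
    h <- !is.na(cl$hsct_years)
    time[h] <- cl$hsct_years[h]
    event[h] <- 0L
  }
  data.frame(patient_id = cl$patient_id, time = time, event = event)
}

#' Kaplan-Meier survival summary
#'
#' Product-limit estimate with Greenwood standard errors (via
#' [survival::survfit()]), the 5-year survival rate (value of the step
#' function at t = 5), and the median survival (first time the curve reaches
#' 0.5; `NA` when it never does).
#'
#' @param times follow-up times.
#' @param events event indicators (1 death, 0 censored).
#' @param horizon time at which the landmark rate is read (default 5 years).
#' @return object of class `km_summary`: `km_times`, `km_survival`,
#'   `greenwood_se`, `five_year_rate`, `median_years`, `n`, `n_events`.
#' @export
km_estimate <- function(times, events, horizon = 5) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  structure(list(km_times = fit$time,
                 km_survival = fit$surv,
                 greenwood_se = fit$std.err * fit$surv,
                 five_year_rate = km_surv_at(fit$time, fit$surv, horizon,
                                             n_events = fit$n.event),
                 median_years = unname(summary(fit)$table["median"]),
                 n = length(times),
                 n_events = sum(events == 1)),
            class = "km_summary")
}

# step-function value S(t): carried (right-continuous) value at t
km_surv_at <- function(times, surv, t, n_events = NULL) {
  idx <- which(times <= t)
  if (!length(idx)) return(1)
  surv[max(idx)]
}

#' @export
print.km_summary <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: n=%d, events=%d\n", x$n, x$n_events))
  cat(sprintf("  5-year survival: %.1f%%\n", 100 * x$five_year_rate))
  cat(sprintf("  median survival: %s years\n",
              ifelse(is.na(x$median_years), "not reached",
                     sprintf("%.2f", x$median_years))))
  invisible(x)
}

#' Log-rank test across survival groups
#'
#' @param groups list of `(times, events)` pairs (each a list or data.frame
#'   with elements `time`/`times` and `event`/`events`), one per group.
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  pull <- function(g, a, b) { v <- g[[a]]; if (is.null(v)) g[[b]] else v }
  times <- lapply(groups, pull, "time", "times")
  events <- lapply(groups, pull, "event", "events")
  if (any(lengths(times) == 0L))
    stop("every group needs at least one observation", call. = FALSE)
  df <- data.frame(time = unlist(times), event = unlist(events),
                   group = rep(seq_along(groups), lengths(times)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(unique(df$group))
  list(chi2 = sd$chisq, df = k - 1,
       p = stats::pchisq(sd$chisq, k - 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Efron tie handling (via
#' [survival::coxph()]); Wald confidence intervals and p-values. Monotone
#' likelihood (perfect separation) surfaces as a warning from the underlying
#' fitter with a capped estimate.
#'
#' @param times,events survival outcome.
#' @param covariates data.frame (or vector) of covariates.
#' @return object of class `cox_result`: `coefficients`, `hazard_ratios`,
#'   `ci95` (matrix with `lower`/`upper`), `p_values`, `fit` (the underlying
#'   `coxph` object).
#' @export
cox_fit <- function(times, events, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(times))
    stop("covariates must match survival times in length", call. = FALSE)
  if (length(times) <= ncol(covariates))
    stop("need more observations than covariates", call. = FALSE)
  const <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "), call. = FALSE)
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) || fit$iter >= 100)
    warning("Cox fit may not have converged")
  sm <- summary(fit)
  structure(list(coefficients = stats::coef(fit),
                 hazard_ratios = exp(stats::coef(fit)),
                 ci95 = cbind(lower = sm$conf.int[, "lower .95"],
                              upper = sm$conf.int[, "upper .95"]),
                 p_values = sm$coefficients[, "Pr(>|z|)"],
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  for (i in seq_along(x$coefficients))
    cat(sprintf("  %-24s HR %.3f (95%% CI %.3f-%.3f), p=%.3g\n",
                names(x$coefficients)[i], x$hazard_ratios[i],
                x$ci95[i, "lower"], x$ci95[i, "upper"], x$p_values[i]))
  invisible(x)
}

#' Map genomic groups to risk categories
#'
#' The fixed six-tier stratification of the genomic groups: DP1 and DP5
#' (JAK2- and CALR-driven MPN-like groups) are very favorable; DP8 and DP10
#' (1q-derivative and SF3B1/DDX41 groups) favorable; DP3 and DP6
#' intermediate; DP4 (TET2/SRSF2) adverse; DP2, DP7 and DP9 (TP53/complex,
#' SETBP1, NPM1) very adverse; DP0 is the no-abnormality reference.
#'
#' @param group_label character vector of labels among `DP0`..`DP10`.
#' @return factor of risk categories.
#' @export
map_risk_categories <- function(group_label) {
  map <- c(DP1 = "very_favorable", DP5 = "very_favorable",
           DP8 = "favorable", DP10 = "favorable",
           DP3 = "intermediate", DP6 = "intermediate",
           DP4 = "adverse",
           DP2 = "very_adverse", DP7 = "very_adverse", DP9 = "very_adverse",
           DP0 = "no_abnormality")
  bad <- setdiff(unique(group_label), names(map))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  factor(unname(map[group_label]),
         levels = c("very_favorable", "favorable", "intermediate",
                    "adverse", "very_adverse", "no_abnormality"))
}

#' Survival report stratified by genomic group and risk category
#'
#' Kaplan-Meier summaries per genomic group and per risk category, log-rank
#' tests across strata, Cox hazard ratios of each risk category against the
#' no-abnormality (DP0) reference, and a univariate-then-multivariate Cox
#' screen of supplied clinical covariates: covariates significant in the
#' univariate model (p < `screen_alpha`) enter the multivariate model
#' together with the risk categories.
#'
#' @param cohort an `mn_cohort`.
#' @param labels named group label (`DP0`..`DP10`) per patient; for a fitted
#'   [dp_cluster()] model use `fit$canonical_labels`, which carries the
#'   paper-style group identities the risk categories are defined on.
#'   Labels outside `DP0`..`DP10` (or `NA`) are kept out of the
#'   category-level analyses.
#' @param censor_at_hsct passed to [prepare_survival()].
#' @param covariates optional data.frame of clinical covariates (rows
#'   aligned with `cohort$clinical`).
#' @param screen_alpha univariate significance level for entry into the
#'   multivariate model.
#' @return list with `by_group` and `by_category` (named lists of
#'   `km_summary`), `logrank_groups`, `logrank_categories`,
#'   `category_hr` (Cox of category dummies vs DP0), `cox_univariate`,
#'   `cox_multivariate`.
#' @export
stratified_report <- function(cohort, labels, censor_at_hsct = TRUE,
                              covariates = NULL, screen_alpha = 0.05) {
  stopifnot(inherits(cohort, "mn_cohort"))
  surv <- prepare_survival(cohort, censor_at_hsct)
  if (!all(surv$patient_id %in% names(labels)))
    stop("labels must cover every patient in the cohort", call. = FALSE)
  lab <- labels[match(surv$patient_id, names(labels))]
  # unidentifiable groups (no canonical identity) get no risk category and
  # are omitted from the category-level analyses
  known <- !is.na(lab) & lab %in% c(paste0("DP", 0:10))
  cat_lab <- factor(rep(NA_character_, length(lab)),
                    levels = levels(map_risk_categories("DP0")))
  cat_lab[known] <- map_risk_categories(lab[known])

  km_by <- function(f) {
    keep <- !is.na(f)
    out <- lapply(split(which(keep), f[keep]), function(idx)
      km_estimate(surv$time[idx], surv$event[idx]))
    out[order(names(out))]
  }
  by_group <- km_by(lab)
  by_category <- km_by(as.character(cat_lab))

  lr <- function(f) {
    keep <- !is.na(f)
    gs <- split(surv[keep, c("time", "event")], f[keep])
    gs <- gs[vapply(gs, function(g) nrow(g) > 0, logical(1))]
    if (length(gs) < 2) return(NULL)
    logrank_test(gs)
  }

  # category hazard ratios against the DP0 reference (patients with a
  # defined category only)
  category_hr <- NULL
  has_cat <- !is.na(cat_lab)
  if (sum(cat_lab[has_cat] == "no_abnormality") > 0 &&
      nlevels(droplevels(cat_lab[has_cat])) > 1) {
    cf <- stats::relevel(droplevels(cat_lab[has_cat]),
                         ref = "no_abnormality")
    dummies <- stats::model.matrix(~cf)[, -1, drop = FALSE]
    colnames(dummies) <- sub("^cf", "", colnames(dummies))
    dummies <- dummies[, colSums(dummies) > 0, drop = FALSE]
    category_hr <- tryCatch(
      cox_fit(surv$time[has_cat], surv$event[has_cat],
              as.data.frame(dummies)),
      error = function(e) NULL)
  }

  cox_uni <- cox_multi <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    uni <- lapply(names(covariates), function(nm)
      tryCatch(cox_fit(surv$time, surv$event, covariates[nm]),
               error = function(e) NULL))
    names(uni) <- names(covariates)
    cox_uni <- uni[!vapply(uni, is.null, logical(1))]
    keep <- names(cox_uni)[vapply(cox_uni, function(f)
      any(f$p_values < screen_alpha), logical(1))]
    if (length(keep)) {
      # risk categories enter the multivariate model alongside the
      # univariate-significant clinical covariates
      rows <- if (is.null(category_hr)) rep(TRUE, nrow(surv)) else has_cat
      multi_x <- covariates[rows, keep, drop = FALSE]
      if (!is.null(category_hr)) {
        cf <- stats::relevel(droplevels(cat_lab[rows]),
                             ref = "no_abnormality")
        dm <- stats::model.matrix(~cf)[, -1, drop = FALSE]
        colnames(dm) <- sub("^cf", "", colnames(dm))
        dm <- dm[, colSums(dm) > 0, drop = FALSE]
        multi_x <- cbind(as.data.frame(dm), multi_x)
      }
      cox_multi <- tryCatch(
        cox_fit(surv$time[rows], surv$event[rows], multi_x),
        error = function(e) NULL)
    }
  }

  list(by_group = by_group,
       by_category = by_category,
       logrank_groups = lr(lab),
       logrank_categories = lr(cat_lab),
       category_hr = category_hr,
       cox_univariate = cox_uni,
       cox_multivariate = cox_multi)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to `horizon` years; reported as the
#' "estimated survival" summary for groups whose median is never reached.
#'
#' @param times,events survival outcome.
#' @param horizon truncation time in years.
#' @return restricted mean survival time in years.
#' @export
restricted_mean_survival <- function(times, events, horizon = 20) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  t <- c(0, fit$time[fit$time <= horizon], horizon)
  s <- c(1, fit$surv[fit$time <= horizon])
  sum(diff(t) * s)
}
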