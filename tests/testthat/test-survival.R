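# brute-force partial-likelihood grid for a single binary covariate
cox_grid_oracle <- function(time, event, x) {
  ll <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  grid <- seq(-4, 4, by = 1e-4)
  grid[which.max(vapply(grid, ll, numeric(1)))]
}

test_that("survival preparation honours the transplant-censoring rule", {
  cl <- toy_clinical(3)
  cl$os_years <- c(3, 3, 2)
  cl$death <- c(TRUE, TRUE, FALSE)
  cl$hsct_years <- c(NA, 1.2, NA)
  coh <- mn_cohort(cl)
  s1 <- prepare_survival(coh, censor_at_hsct = TRUE)
  expect_equal(s1$time, c(3, 1.2, 2))
  expect_equal(s1$event, c(1L, 0L, 0L))
  s2 <- prepare_survival(coh, censor_at_hsct = FALSE)
  expect_equal(s2$time, c(3, 3, 2))
  expect_equal(s2$event, c(1L, 1L, 0L))
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  k <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$km_survival, c(2 / 3, 1 / 3, 0))
  expect_equal(k$median_years, 2)

  # censoring keeps the curve flat and shrinks the risk set
  k2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k2$km_survival[k2$km_times == 1], 2 / 3)
  expect_equal(k2$km_survival[k2$km_times == 3], 0)

  k3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(k3$km_survival == 1))
  expect_true(is.na(k3$median_years))
  expect_equal(k3$five_year_rate, 1)

  # five-year rate is the carried step value at t = 5
  k4 <- km_estimate(c(2, 4, 6, 8), c(1, 1, 1, 1))
  expect_equal(k4$five_year_rate, 0.5)
})

test_that("log-rank behaves at both extremes and under the null", {
  same <- list(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  lr <- logrank_test(list(same, same))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  g1 <- list(time = rep(1, 20), event = rep(1, 20))
  g2 <- list(time = rep(10, 20), event = rep(1, 20))
  expect_lt(logrank_test(list(g1, g2))$p, 1e-6)
  expect_error(logrank_test(list(g1)), "two groups")
  expect_error(logrank_test(list(g1, list(time = numeric(),
                                          event = numeric()))),
               "at least one observation")

  # permuted labels with no effect give uniform p-values
  set.seed(123)
  pvals <- vapply(1:400, function(s) {
    t <- rexp(100, 0.2); e <- rbinom(100, 1, 0.8)
    grp <- sample(rep(1:2, 50))
    logrank_test(list(list(time = t[grp == 1], event = e[grp == 1]),
                      list(time = t[grp == 2], event = e[grp == 2])))$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Cox fit matches the partial-likelihood grid oracle", {
  t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- cox_fit(t, e, data.frame(x = x))
  expect_equal(unname(fit$coefficients), cox_grid_oracle(t, e, x),
               tolerance = 1e-4)
  # partial likelihood depends on time ranks only
  fit2 <- cox_fit(2 * t, e, data.frame(x = x))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-8)
  expect_equal(unname(fit$hazard_ratios), exp(unname(fit$coefficients)))
  expect_error(cox_fit(t, e, data.frame(x = rep(1, 4))), "constant")

  set.seed(31)
  n <- 2000
  xx <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.1)
  fit3 <- cox_fit(tt, rep(1, n), data.frame(arm = xx))
  expect_gt(unname(fit3$hazard_ratios), 0.9)
  expect_lt(unname(fit3$hazard_ratios), 1.1)
})

test_that("risk-category mapping is total and exact", {
  expected <- c(DP0 = "no_abnormality",
                DP1 = "very_favorable", DP5 = "very_favorable",
                DP8 = "favorable", DP10 = "favorable",
                DP3 = "intermediate", DP6 = "intermediate",
                DP4 = "adverse",
                DP2 = "very_adverse", DP7 = "very_adverse",
                DP9 = "very_adverse")
  got <- map_risk_categories(names(expected))
  expect_equal(as.character(got), unname(expected))
  expect_error(map_risk_categories("DP11"), "unknown group")
})

test_that("stratified report screens covariates and orders risk correctly", {
  run <- fixture_default_run()
  rep_all <- stratified_report(run$cohort, run$fit$canonical_labels)
  vf <- rep_all$by_category[["very_favorable"]]$five_year_rate
  va <- rep_all$by_category[["very_adverse"]]$five_year_rate
  expect_gt(vf, va)
  expect_lt(rep_all$logrank_categories$p, 1e-10)
  expect_false(is.null(rep_all$category_hr))
  hr <- rep_all$category_hr$hazard_ratios
  expect_gt(hr[["very_adverse"]], hr[["very_favorable"]])

  # single-stratum cohort
  cl <- toy_clinical(30)
  cl$os_years <- rexp(30, 0.2) + 0.1
  cl$death <- rep(c(TRUE, FALSE), 15)
  coh <- mn_cohort(cl)
  labs <- stats::setNames(rep("DP1", 30), cl$patient_id)
  rep1 <- stratified_report(coh, labs)
  expect_length(rep1$by_group, 1)
  expect_null(rep1$logrank_groups)

  # univariate screening: an informative covariate enters the multivariate
  # model, pure noise does not
  set.seed(77)
  n <- 400
  age <- rnorm(n, 60, 10)
  noise <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.06 * (age - 60)))
  cl2 <- toy_clinical(n)
  cl2$os_years <- t
  cl2$death <- TRUE
  coh2 <- mn_cohort(cl2)
  labs2 <- stats::setNames(rep(c("DP0", "DP1"), n / 2), cl2$patient_id)
  rep2 <- stratified_report(coh2, labs2,
                            covariates = data.frame(age = age,
                                                    noise = noise))
  expect_true("age" %in% names(rep2$cox_multivariate$coefficients))
  expect_false("noise" %in% names(rep2$cox_multivariate$coefficients))
})

test_that("restricted mean survival equals the exponential closed form", {
  set.seed(5)
  t <- rexp(20000, 0.5)
  rm <- restricted_mean_survival(t, rep(1, 20000), horizon = 10)
  expect_equal(rm, (1 - exp(-5)) / 0.5, tolerance = 0.05)
})
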