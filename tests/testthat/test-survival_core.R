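test_that("Kaplan-Meier estimate matches hand product-limit calculations", {
  # single death
  km <- km_estimate(100)
  expect_equal(km$time, 100)
  expect_equal(km$surv, 0)

  # uncensored: equals the empirical survival function
  km <- km_estimate(c(2, 4, 4, 6))
  expect_equal(km$time, c(2, 4, 6))
  expect_equal(km$surv, c(0.75, 0.25, 0))
  expect_equal(km$n_risk, c(4L, 3L, 1L))
  expect_equal(km$n_event, c(1L, 2L, 1L))

  # censoring: (1 - 1/3) * (1 - 1/1)
  km <- km_estimate(c(2, 3, 4), event = c(TRUE, FALSE, TRUE))
  expect_equal(km$surv, c(2 / 3, 0))

  # all censored: constant 1 with warning
  expect_warning(km0 <- km_estimate(c(1, 2), event = c(FALSE, FALSE)),
                 "censored")
  expect_length(km0$surv, 0)
})

test_that("Kaplan-Meier agrees with the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(42)
  time <- round(stats::rweibull(60, 2, 800)) + 1
  event <- stats::runif(60) < 0.8
  km <- km_estimate(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  expect_equal(km$time, sf$time[keep])
  expect_equal(km$surv, sf$surv[keep], tolerance = 1e-12)
})

test_that("median lifespan follows the first-time-at-or-below-half convention", {
  expect_equal(median_lifespan(5), 5)
  expect_equal(median_lifespan(c(1, 2, 3)), 2)
  expect_equal(median_lifespan(c(1, 2, 3, 4)), 2)  # S(2) = 0.5 exactly
  km <- suppressWarnings(km_estimate(c(1, 2), event = c(FALSE, FALSE)))
  expect_error(median_lifespan(km), class = "lifespanr_undefined_median")

  # uncensored: equals exhaustive scan of the empirical survival function
  set.seed(9)
  for (i in 1:20) {
    x <- sample(1:50, sample(3:15, 1), replace = TRUE)
    s <- vapply(sort(unique(x)), function(t) mean(x > t), 0)
    expect_equal(median_lifespan(x), sort(unique(x))[which(s <= 0.5)[1]])
  }
})

test_that("percent change reproduces printed lifespan arithmetic", {
  pc <- percent_change(1004, 839)
  expect_equal(pc$days, 165)
  expect_equal(round(pc$percent), 16)
  pc <- percent_change(1011, 807)
  expect_equal(pc$days, 204)
  expect_equal(round(pc$percent), 20)
  pc <- percent_change(880, 880)
  expect_equal(pc$days, 0)
  expect_equal(pc$percent, 0)
  expect_error(percent_change(0, 10), class = "lifespanr_validation_error")
})

test_that("log-rank accumulations match hand computation and are label-symmetric", {
  # duplicated group: statistic 0, p 1
  x <- c(10, 20, 30)
  lr <- logrank_test(x, x)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p.value, 1)

  # hand accumulation for A = {1,2}, B = {3,4}
  lr <- logrank_test(c(1, 2), c(3, 4))
  expect_equal(lr$observed[["a"]], 2)
  expect_equal(lr$expected[["a"]], 1 / 2 + 1 / 3, tolerance = 1e-12)
  expect_equal(lr$variance, 1 / 4 + 2 / 9, tolerance = 1e-12)
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9),
               tolerance = 1e-12)
  expect_equal(lr$statistic, 2.88, tolerance = 0.01)

  # label swap leaves statistic and p unchanged
  set.seed(3)
  ta <- stats::runif(12, 100, 900); tb <- stats::runif(9, 100, 900)
  lr1 <- logrank_test(ta, tb); lr2 <- logrank_test(tb, ta)
  expect_equal(lr1$statistic, lr2$statistic)
  expect_equal(lr1$p.value, lr2$p.value)

  # invariance under strictly monotone age transforms
  lr3 <- logrank_test(ta^2, tb^2)
  expect_equal(lr1$statistic, lr3$statistic, tolerance = 1e-12)

  # degenerate single shared death time
  expect_warning(lr0 <- logrank_test(5, 5), "degenerate")
  expect_equal(lr0$p.value, 1)
})

test_that("log-rank agrees with survdiff on tied and censored data", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (i in 1:10) {
    ta <- sample(1:30, 15, replace = TRUE)
    tb <- sample(1:30, 12, replace = TRUE)
    lr <- logrank_test(ta, tb)
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb)) ~ rep(1:2, c(15, 12)))
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  }
})

test_that("Cox fit maximises the partial likelihood (grid oracle, no ties)", {
  # A deaths {1,3} carry x = 1; B deaths {2,4} carry x = 0
  time <- c(1, 3, 2, 4); x <- c(1, 1, 0, 0)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b)
    log(exp(b) / (2 * exp(b) + 2)) + log(1 / (exp(b) + 2)) +
      log(exp(b) / (exp(b) + 1)), 0)
  beta_grid <- grid[which.max(ll)]
  fit <- cox_ph_fit(x, time)
  expect_equal(unname(fit$coefficients), beta_grid, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(unname(fit$hazard_ratios), exp(unname(fit$coefficients)))
  # naive double-loop likelihood oracle agrees at the optimum
  opt <- stats::optimize(function(b) cox_loglik_naive(b, x, time),
                         c(-3, 3), maximum = TRUE)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-4)
})

test_that("Cox fit agrees with survival::coxph under both tie methods", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 120
  x <- cbind(trt = stats::rbinom(n, 1, 0.5), z = stats::rnorm(n))
  time <- round(stats::rexp(n, 0.02 * exp(0.6 * x[, 1] - 0.3 * x[, 2]))) + 1
  event <- stats::runif(n) < 0.9
  for (ties in c("efron", "breslow")) {
    fit <- cox_ph_fit(x, time, event, ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties)
    expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(fit$loglik[["max"]], ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("Cox fit recovers a known hazard ratio on simulated data", {
  set.seed(31)
  n <- 2000
  x <- stats::rbinom(n, 1, 0.5)
  time <- stats::rexp(n, 0.005 * exp(log(2) * x))
  fit <- cox_ph_fit(x, time)
  expect_lt(abs(unname(fit$coefficients) - log(2)), 0.1)
})

test_that("degenerate covariates are rejected; separation is flagged", {
  expect_error(cox_ph_fit(rep(1, 5), 1:5),
               class = "lifespanr_validation_error")
  # covariate perfectly ordered with death times: monotone likelihood
  expect_warning(fit <- cox_ph_fit(c(1, 1, 1, 0, 0, 0), c(1, 2, 3, 4, 5, 6)),
                 "monotone|converge")
  expect_false(fit$converged)
})

test_that("linear lifespan model reproduces group means and orthogonality", {
  co <- cohort(paste0("m", 1:4), c(10, 20, 30, 50),
               genotype = "dwarf",
               treatment = c("saline", "saline", "GH", "GH"),
               sex = "male")
  fit <- lifespan_linear_model(co, adjust_sex = FALSE)
  expect_equal(unname(fit$coefficients["treatmentGH"]), 25)
  expect_equal(unname(fit$adjusted_means),
               c(15, 40))
  expect_equal(sum(stats::residuals(fit$model)), 0, tolerance = 1e-10)

  # balanced sex covariate leaves the treatment effect untouched
  co2 <- cohort(paste0("m", 1:8), c(10, 20, 30, 50, 12, 22, 32, 52),
                genotype = "dwarf",
                treatment = rep(c("saline", "saline", "GH", "GH"), 2),
                sex = rep(c("male", "female"), each = 4))
  f1 <- lifespan_linear_model(co2, adjust_sex = FALSE)
  f2 <- lifespan_linear_model(co2, adjust_sex = TRUE)
  expect_equal(f1$coefficients["treatmentGH"], f2$coefficients["treatmentGH"],
               tolerance = 1e-10)

  # saturated model on a larger cohort still returns cell means exactly
  co3 <- random_cohort(80, seed = 5)
  f3 <- lifespan_linear_model(co3, adjust_sex = FALSE)
  means <- tapply(co3$age_days, co3$treatment, mean)
  expect_equal(unname(f3$adjusted_means["saline"]), unname(means[["saline"]]))
  expect_equal(unname(f3$adjusted_means["GH"]), unname(means[["GH"]]))

  # censored records are refused; single-treatment cohorts are rank-deficient
  cen <- cohort("c1", 100, "dwarf", "GH", "male", event = FALSE)
  expect_error(lifespan_linear_model(cen),
               class = "lifespanr_validation_error")
  solo <- cohort(paste0("s", 1:4), c(5, 6, 7, 8), "dwarf", "GH", "male")
  expect_error(lifespan_linear_model(solo, adjust_sex = FALSE),
               "treatment", class = "lifespanr_validation_error")
})
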