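test_that("parameter objects enforce their ranges", {
  expect_s3_class(gompertz_params(1e-5, 0.01, 1e-4), "gompertz_params")
  expect_error(gompertz_params(0, 0, 0), class = "lifespanr_validation_error")
  expect_error(gompertz_params(-1e-5), class = "lifespanr_validation_error")
  expect_error(gompertz_params(1e-5, -0.01), class = "lifespanr_validation_error")
})

test_that("b = 0 reduces to an exponential lifespan distribution", {
  a <- 1 / 300
  x <- simulate_gompertz_makeham(gompertz_params(a, 0), 1e5, seed = 101)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 1 / a), 3 * se)
})

test_that("simulated medians match the closed-form median", {
  params <- gompertz_params(2e-5, 0.008)
  x <- simulate_gompertz_makeham(params, 1e4, seed = 202)
  boot <- replicate(200, stats::median(sample(x, replace = TRUE)))
  expect_lt(abs(stats::median(x) - theoretical_median(params)),
            3 * stats::sd(boot))
})

test_that("theoretical_median matches numeric inversion and closed-form limits", {
  # near-exponential limit: median -> log(2)/a
  p <- gompertz_params(log(2), 1e-12)
  expect_equal(theoretical_median(p), 1, tolerance = 1e-6)

  # pure Gompertz closed form vs independent bisection of S(t) = 0.5
  params <- gompertz_params(2e-5, 0.008)
  bisect <- function(lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (gompertz_survival(mid, params) > 0.5) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  m <- theoretical_median(params)
  expect_equal(m, bisect(1, 5000), tolerance = 1e-6)

  # doubling a strictly decreases the median; monotone in hazard scale
  expect_lt(theoretical_median(gompertz_params(4e-5, 0.008)), m)

  # Makeham case: numeric root agrees with direct survival evaluation
  pm <- gompertz_params(2e-5, 0.008, 5e-4)
  expect_equal(gompertz_survival(theoretical_median(pm), pm), 0.5,
               tolerance = 1e-8)
})

test_that("inverse-CDF sampling reproduces the survival law (KS) and is seed-stable", {
  params <- gompertz_params(2e-5, 0.008)
  cdf <- function(q) 1 - gompertz_survival(q, params)
  x1 <- simulate_gompertz_makeham(params, 1e4, seed = 303)
  x2 <- simulate_gompertz_makeham(params, 1e4, seed = 303)
  expect_identical(x1, x2)
  expect_gt(stats::ks.test(x1, cdf)$p.value, 0.01)

  # Makeham branch (Newton inversion) also matches its own law
  pm <- gompertz_params(2e-5, 0.008, 5e-4)
  xm <- simulate_gompertz_makeham(pm, 1e4, seed = 304)
  expect_gt(stats::ks.test(xm, function(q) 1 - gompertz_survival(q, pm))$p.value,
            0.01)

  # larger b stochastically shortens life at fixed a
  x_fast <- simulate_gompertz_makeham(gompertz_params(2e-5, 0.012), 1e4,
                                      seed = 305)
  expect_lt(stats::median(x_fast), stats::median(x1))
})

test_that("study cohorts honour the design template exactly", {
  co1 <- build_study_cohort(paper_like_design("week1", seed = 7))
  expect_identical(nrow(co1), 149L)
  co2 <- build_study_cohort(paper_like_design("week2", seed = 7))
  expect_identical(nrow(co2), 123L)
  expect_true(all(co1$event))

  one <- study_design(data.frame(genotype = "dwarf", treatment = "saline",
                                 sex = "female", n = 5,
                                 a = 2e-5, b = 0.008, c = 0), seed = 1)
  co <- build_study_cohort(one)
  expect_identical(nrow(co), 5L)
  expect_true(all(co$genotype == "dwarf" & co$treatment == "saline" &
                  co$sex == "female"))

  expect_error(study_design(data.frame(), seed = 1),
               class = "lifespanr_validation_error")
})

test_that("cell substreams are independent: adding a cell never perturbs others", {
  base <- data.frame(genotype = "dwarf", treatment = c("saline", "GH"),
                     sex = "male", n = 10, a = 2e-5, b = 0.008, c = 0)
  extra <- rbind(base, data.frame(genotype = "control", treatment = "saline",
                                  sex = "female", n = 10,
                                  a = 2e-5, b = 0.008, c = 0))
  co_base <- build_study_cohort(study_design(base, seed = 99))
  co_extra <- build_study_cohort(study_design(extra, seed = 99))
  for (trt in c("saline", "GH")) {
    expect_identical(
      co_base$age_days[co_base$treatment == trt & co_base$genotype == "dwarf"],
      co_extra$age_days[co_extra$treatment == trt & co_extra$genotype == "dwarf"])
  }
})

test_that("median calibration and hazard scaling behave as documented", {
  p <- gompertz_from_median(1004, b = 0.008)
  expect_equal(theoretical_median(p), 1004, tolerance = 1e-9)
  p2 <- scale_hazard(p, 2)
  expect_equal(p2$a, 2 * p$a)
  expect_lt(theoretical_median(p2), theoretical_median(p))
  expect_error(gompertz_from_median(1000, b = 0.008, c = 0.01),
               class = "lifespanr_validation_error")
})

test_that("rounding to whole days is an explicit output option", {
  des <- study_design(data.frame(genotype = "dwarf", treatment = "saline",
                                 sex = "male", n = 50,
                                 a = 2e-5, b = 0.008, c = 0), seed = 5)
  co <- build_study_cohort(des, round_days = TRUE)
  expect_true(all(co$age_days == round(co$age_days)))
  expect_true(all(co$age_days >= 1))
  co_cont <- build_study_cohort(des)
  expect_false(all(co_cont$age_days == round(co_cont$age_days)))
})
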