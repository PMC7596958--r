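test_that("covariate-free fit reduces to the Nelson-Aalen estimator", {
  fit <- fitCoxNull(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_length(coef(fit), 0)
  expect_equal(fit@baseline$hazard, c(1 / 4, 1 / 3, 1 / 2, 1))
  expect_equal(fit@baseline$cumhaz, cumsum(c(1 / 4, 1 / 3, 1 / 2, 1)))
  # earliest event: residual = 1 - 1/4
  mr <- martingaleResiduals(fit, c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(mr[1], 0.75)
  # censored before the first event: cumulative hazard 0, residual 0
  expect_equal(martingaleResiduals(fit, 0.5, 0L), 0)
})

test_that("Cox fit matches the survival package to 1e-6 and recovers beta = 0", {
  skip_if_not_installed("survival")
  d <- makeSurvData(2000, seed = 11, betas = c(0, 0))
  fit <- fitCoxNull(d$time, d$status, covariates = d$covariates)
  cf <- survival::coxph(survival::Surv(d$time, d$status) ~ x1 + x2,
                        data = d$covariates, ties = "breslow")
  expect_lt(max(abs(coef(fit) - coef(cf))), 1e-6)
  expect_lt(abs(fit@loglik - cf$loglik[2]), 1e-6)
  # true beta is 0: the estimate must sit within 3 standard errors
  expect_lt(max(abs(coef(fit)) / sqrt(diag(vcov(fit)))), 3)
})

test_that("martingale residuals match the survival package and sum to zero", {
  skip_if_not_installed("survival")
  d <- makeSurvData(500, seed = 12)
  fit <- fitCoxNull(d$time, d$status, covariates = d$covariates)
  mr <- martingaleResiduals(fit, d$time, d$status, covariates = d$covariates)
  cf <- survival::coxph(survival::Surv(d$time, d$status) ~ x1 + x2,
                        data = d$covariates, ties = "breslow")
  expect_lt(max(abs(mr - residuals(cf, type = "martingale"))), 1e-6)
  expect_lt(abs(sum(mr)), 1e-8 * length(mr))
  expect_lte(max(mr), 1)
})

test_that("fit is invariant to subject ordering and validates its input", {
  d <- makeSurvData(120, seed = 13)
  fit <- fitCoxNull(d$time, d$status, covariates = d$covariates)
  p <- withr::with_seed(1, sample(120))
  fit2 <- fitCoxNull(d$time[p], d$status[p], covariates = d$covariates[p, ])
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-9)
  expect_equal(fit@loglik, fit2@loglik, tolerance = 1e-9)

  expect_error(fitCoxNull(c(1, 2, 3), c(0, 0, 0)), "no events")
  expect_error(
    fitCoxNull(d$time, d$status,
               covariates = cbind(d$covariates, x3 = d$covariates$x1)),
    "collinear")
})

test_that("log-rank agrees with hand computation, survdiff, and is zero for identical curves", {
  # duplicated data in both groups: curves identical, statistic 0
  lr0 <- logrankTest(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                     rep(c(0, 1), each = 3))
  expect_equal(lr0@statistic, 0)

  # hand-built 4-subject risk tables: group A events at 1,2; B at 3,4.
  # O1-E1 for A = (1 - 2/4) + (1 - 1/3) = 7/6; V = 1/4 + 2/9
  lr <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(sum(lr@observed - lr@expected), 7 / 6)
  expect_equal(lr@variance, 1 / 4 + 2 / 9)
  expect_equal(lr@statistic, (7 / 6) / sqrt(1 / 4 + 2 / 9))

  skip_if_not_installed("survival")
  d <- makeSurvData(200, seed = 14)
  g <- withr::with_seed(15, rbinom(200, 1, 0.5))
  lr2 <- logrankTest(d$time, d$status, g)
  sd2 <- survival::survdiff(survival::Surv(d$time, d$status) ~ g)
  expect_lt(abs(lr2@chisq - sd2$chisq), 1e-6)

  expect_error(logrankTest(d$time, d$status, rep(1, 200)),
               "degenerate grouping")
})

test_that("Kaplan-Meier curves match closed forms and survfit", {
  km <- kmCurve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(3 / 4, 1 / 2, 1 / 4, 0))
  expect_equal(km$nRisk, c(4, 3, 2, 1))

  # all censored: no event rows, survival stays 1 everywhere
  kmc <- kmCurve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(kmc), 0)

  skip_if_not_installed("survival")
  d <- makeSurvData(300, seed = 16)
  km2 <- kmCurve(d$time, d$status)
  sf <- summary(survival::survfit(survival::Surv(d$time, d$status) ~ 1),
                times = km2$time)
  expect_lt(max(abs(km2$survival - sf$surv)), 1e-10)

  expect_error(
    kmCurve(d$time, d$status,
            group = factor(rep("a", 300), levels = c("a", "b"))),
    "empty group")
})
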