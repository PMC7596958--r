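test_that("GenoSurvExperiment validates genotype and outcome coding", {
  g <- makeGeno(10, 4, seed = 111)
  gse <- withr::with_seed(111,
    GenoSurvExperiment(g, time = runif(10, 40, 80),
                       status = rbinom(10, 1, 0.5),
                       covariates = data.frame(smoking = rbinom(10, 1, 0.4))))
  expect_identical(unname(genotypes(gse)), unname(g))
  expect_length(eventTime(gse), 10)
  expect_equal(colnames(covariateMatrix(gse)), "smoking")
  expect_true(all(snpMAF(gse) >= 0 & snpMAF(gse) <= 0.5))

  bad <- g; bad[1, 1] <- 5L
  expect_error(GenoSurvExperiment(bad), "0, 1, 2 or NA")
  expect_error(GenoSurvExperiment(g, time = c(-1, rep(1, 9))),
               "nonnegative")
  expect_error(GenoSurvExperiment(g, time = rep(1, 10),
                                  status = rep(2L, 10)), "status")
})

test_that("penetrance model validity enforces its invariants", {
  pm <- makePenetrance(0.3, 0.1, seed = 112)
  expect_s4_class(pm, "PenetranceModel")
  # tampering with the table breaks the no-main-effect constraint
  broken <- pm
  broken@f[1, 1] <- min(1, broken@f[1, 1] + 0.2)
  expect_error(validObject(broken), "marginal")
})

test_that("show methods render without error", {
  g <- makeGeno(10, 4, seed = 113)
  gse <- withr::with_seed(113,
    GenoSurvExperiment(g, time = runif(10, 1, 3),
                       status = c(1L, rbinom(9, 1, 0.7))))
  expect_output(show(gse), "GenoSurvExperiment")
  fit <- fitCoxNull(gse)
  expect_output(show(fit), "CoxNullFit")
  pm <- makePenetrance(0.2, 0.05, seed = 114)
  expect_output(show(pm), "PenetranceModel")
  sim <- simulateNull(m = 5, n = 60, seed = 115)
  res <- esmdrSearch(sim$genotype, sim$outcome, k = 1, seed = 116)
  expect_output(show(res), "MDRResult")
  expect_output(show(logrankTest(eventTime(gse), eventStatus(gse),
                                 rep(c(0, 1), 5))), "Log-rank")
})
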