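test_that("null generator matches its declared distributions", {
  sim <- simulateNull(m = 20, n = 2000, seed = 71)
  expect_true(all(sim$maf >= 0.1 & sim$maf <= 0.5))
  # sample allele frequency within 3 binomial SE of the drawn MAF
  for (j in seq_len(20)) {
    p <- mean(sim$genotype[, j]) / 2
    se <- sqrt(sim$maf[j] * (1 - sim$maf[j]) / (2 * 2000))
    expect_lt(abs(p - sim$maf[j]), 3 * se + 1e-12)
  }
  # outcome independent of genotypes by construction
  cors <- abs(cor(sim$genotype, sim$outcome))
  expect_lt(max(cors), 4 / sqrt(2000))
  # reproducibility contract
  sim2 <- simulateNull(m = 20, n = 2000, seed = 71)
  expect_identical(sim$genotype, sim2$genotype)
  expect_identical(sim$outcome, sim2$outcome)
})

test_that("penetrance tables are purely epistatic at the exact heritability", {
  for (cfg in list(c(0.2, 0.05), c(0.4, 0.4), c(0.2, 0.3), c(0.2, 0.4))) {
    pm <- makePenetrance(cfg[1], cfg[2], seed = 72)
    w <- esmdr:::hweWeights(cfg[1])
    K <- pm@prevalence
    # no main effects: both weighted marginals equal the prevalence
    expect_lt(max(abs(pm@f %*% w - K)), 1e-3)
    expect_lt(max(abs(w %*% pm@f - K)), 1e-3)
    # brute-force 9-cell recomputation of the achieved heritability
    h2 <- 0
    for (i in 1:3) for (j in 1:3)
      h2 <- h2 + w[i] * w[j] * (pm@f[i, j] - K)^2 / (K * (1 - K))
    expect_equal(h2, pm@h2, tolerance = 1e-10)
    expect_lt(abs(pm@h2 - cfg[2]) / cfg[2], 0.05)
    expect_true(all(pm@f >= 0 & pm@f <= 1))
  }
})

test_that("epistatic survival generator hits its design margins", {
  pm <- makePenetrance(0.4, 0.2, seed = 73)
  gse <- simulateEpistatic(pm, n = 2000, seed = 74)
  risk <- S4Vectors::metadata(gse)$riskClass
  expect_equal(sum(risk), 1000)
  # genotype marginals carry no risk signal (pure epistasis survives the
  # balanced resampling)
  g1 <- genotypes(gse)[, 1]
  tab <- table(g1, risk)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 1e-4)
  # strong beta separates the risk classes in median event age
  evtHigh <- eventTime(gse)[risk == 1 & eventStatus(gse) == 1]
  evtLow <- eventTime(gse)[risk == 0 & eventStatus(gse) == 1]
  expect_lt(median(evtHigh), median(evtLow))
  # with censoring pushed out of range, medians follow the closed-form
  # Weibull PH quantile ratio (e^beta)^{1/shape}
  gse2 <- simulateEpistatic(pm, n = 4000, censorMax = 1e6, seed = 79)
  risk2 <- S4Vectors::metadata(gse2)$riskClass
  med <- tapply(eventTime(gse2), risk2, median)
  expect_equal(unname(med["0"] / med["1"]), exp(1.5 / 5), tolerance = 0.05)
})

test_that("with beta = 0 the risk classes share one survival curve", {
  pm <- makePenetrance(0.2, 0.1, seed = 75)
  pvals <- sapply(1:20, function(s) {
    gse <- simulateEpistatic(pm, n = 300, beta = 0, seed = 75 + s)
    risk <- S4Vectors::metadata(gse)$riskClass
    lr <- logrankTest(eventTime(gse), eventStatus(gse), risk)
    2 * pnorm(-abs(lr@statistic))
  })
  expect_gt(ks.test(pvals, punif)$p.value, 0.01)
})

test_that("type-I error estimator is calibrated on a small run", {
  r <- estimateTypeIError(m = 10, n = 200, reps = 150, k = 1, seed = 76)
  expect_true(r$rate > 1 && r$rate < 11)   # ~5% within MC noise
  sc <- attr(r, "scores")
  expect_equal(dim(sc), c(150L, 1L))
  # empirical threshold mode: by construction 5% of scores exceed it
  r2 <- estimateTypeIError(m = 10, n = 200, reps = 150, k = 1,
                           thresholdMode = "empirical", seed = 76)
  expect_equal(r2$rate, 100 * mean(sc > quantile(sc, 0.95)), tolerance = 1e-8)
})

test_that("power estimator separates strong from null signal", {
  # near-saturated regime: large n, high heritability
  strong <- estimatePower(maf = 0.4, h2 = 0.4, n = 1600, reps = 12,
                          seed = 77)
  expect_true(all(strong$power[strong$mode == "flexible"] >= 0.75))
  expect_true(all(strong$power[strong$mode == "stringent"] >= 0.5))
  weak <- estimatePower(maf = 0.4, h2 = 0.01, n = 400, reps = 15, seed = 78,
                        method = "esmdr")
  expect_true(all(weak$power <= 0.3))
})
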