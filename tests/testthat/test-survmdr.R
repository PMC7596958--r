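# The log-rank-based survival MDR baseline.

test_that("both methods recover a strong epistatic pair on shared data", {
  pm <- makePenetrance(0.4, 0.4, seed = 61)
  gse <- simulateEpistatic(pm, n = 600, beta = 3, seed = 62)
  geno <- genotypes(gse)
  tm <- eventTime(gse)
  st <- eventStatus(gse)
  resid <- martingaleResiduals(fitCoxNull(tm, st), tm, st)
  es <- esmdrSearch(geno, resid, k = 2, seed = 63)
  sm <- survmdrSearch(geno, tm, st, k = 2, seed = 63)
  # shared fold seed and labeling residuals: both scans find the
  # functional pair, on different score scales (t vs squared log-rank)
  expect_identical(bestModel(es, 2)$snps, "SNP1,SNP2")
  expect_identical(bestModel(sm, 2)$snps, "SNP1,SNP2")
  expect_false(isTRUE(all.equal(es@models$testScore, sm@models$testScore)))
})

test_that("Surv-MDR scores are squared log-rank statistics of the pooled grouping", {
  pm <- makePenetrance(0.4, 0.3, seed = 64)
  gse <- simulateEpistatic(pm, n = 200, seed = 65)
  geno <- genotypes(gse)
  tm <- eventTime(gse)
  st <- eventStatus(gse)
  resid <- martingaleResiduals(fitCoxNull(tm, st), tm, st)

  # recompute one model's fold statistic by hand with survival_core tools
  fold <- esmdr:::withSeed(66L, sample(rep_len(1:2, 200)))
  cellsAll <- assignCells(geno, 1:2)
  train <- fold != 1
  trCells <- structure(cellsAll[train], k = 2L)
  labs <- labelCells(trCells, resid[train])
  teCells <- structure(cellsAll[!train], k = 2L)
  teLab <- applyCellLabels(labs, teCells, residuals = resid[!train])
  lr <- logrankTest(tm[!train], st[!train], teLab)
  # group 1 of the log-rank is "HIGH" (alphabetical); signed C statistic
  cf <- sum(lr@observed - lr@expected) / sqrt(lr@variance)

  sm <- survmdrSearch(geno, tm, st, k = 2, seed = 66)
  row <- which(sm@models$snps == "SNP1,SNP2")
  # the model's combined statistic is (sum_f C_f / sqrt(2))^2; recompute
  # the second fold symmetrically
  train2 <- fold != 2
  labs2 <- labelCells(structure(cellsAll[train2], k = 2L), resid[train2])
  teLab2 <- applyCellLabels(labs2, structure(cellsAll[!train2], k = 2L),
                            residuals = resid[!train2])
  lr2 <- logrankTest(tm[!train2], st[!train2], teLab2)
  cf2 <- sum(lr2@observed - lr2@expected) / sqrt(lr2@variance)
  expect_equal(sm@models$testScore[row], ((cf + cf2) / sqrt(2))^2,
               tolerance = 1e-10)
})

test_that("degenerate one-group pooling scores zero", {
  g <- matrix(rep(0:2, length.out = 90), ncol = 1,
              dimnames = list(NULL, "S1"))
  tm <- withr::with_seed(67, rexp(90) + 0.1)
  st <- rep(1L, 90)
  resid <- abs(martingaleResiduals(fitCoxNull(tm, st), tm, st)) + 1
  res <- suppressWarnings(
    esmdr:::mdrEngine(g, resid, k = 1, folds = 2, seed = 68,
                      method = "survmdr", time = tm, status = st))
  expect_equal(res@models$testScore, 0)
})

test_that("permuted-label null scores follow chi-square(1)", {
  set.seed(69)
  scores <- replicate(300, {
    n <- 120
    tm <- rexp(n); cens <- runif(n, 0, 2)
    time <- pmin(tm, cens); status <- as.integer(tm <= cens)
    g <- makeGeno(n, 1, seed = sample.int(1e6, 1))
    sm <- survmdrSearch(g, time, status, k = 1,
                        seed = sample.int(1e6, 1))
    sm@models$testScore
  })
  # approximate chi-square(1) reference; the two-fold combination couples
  # the fold statistics slightly, so the tail sits a little above 5%
  tail <- mean(scores > qchisq(0.95, 1))
  expect_gt(tail, 0.02)
  expect_lt(tail, 0.12)
  expect_lt(abs(median(scores) - qchisq(0.5, 1)), 0.3)
})

test_that("log-rank cell labels match residual-sum labels and risk-set logic", {
  # a cell with uniformly earlier events is high-risk
  time <- c(0.5, 0.7, 0.9, 2, 2.5, 3)
  status <- rep(1L, 6)
  cells <- structure(c(0L, 0L, 0L, 1L, 1L, 1L), k = 1L)
  lab <- survmdrLabelCells(cells, time, status)
  expect_equal(unname(lab), c("HIGH", "LOW", "EMPTY"))

  # dual-route equivalence on censored data with ties
  set.seed(121)
  n <- 180
  g <- makeGeno(n, 2, seed = 122)
  evt <- rexp(n); cens <- runif(n, 0, 2)
  tm <- round(pmin(evt, cens), 1)
  st <- as.integer(evt <= cens)
  cells2 <- assignCells(g, 1:2)
  mr <- martingaleResiduals(fitCoxNull(tm, st), tm, st)
  expect_identical(survmdrLabelCells(cells2, tm, st), labelCells(cells2, mr))
})
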