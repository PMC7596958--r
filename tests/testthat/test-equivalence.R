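# The identity that makes the method work: for residuals from the
# covariate-free Cox null fit, the sum of martingale residuals over any
# subject group equals the log-rank O - E numerator for that group (the
# log-rank statistic with its variance set to 1).

test_that("martingale residual sums reproduce the log-rank numerator exactly", {
  set.seed(401)
  for (d in 1:50) {
    n <- sample(10:40, 1)
    evt <- rexp(n)
    cens <- runif(n, 0, quantile(evt, 0.8))
    time <- pmin(evt, cens)
    status <- as.integer(evt <= cens)
    if (sum(status) < 2) next
    # duplicate a few times so tied event times get exercised
    time <- round(time, 1)
    fit <- fitCoxNull(time, status)
    mr <- martingaleResiduals(fit, time, status)
    for (g in 1:4) {
      grp <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(grp)) < 2) next
      lr <- logrankTest(time, status, grp)
      oe <- sum(lr@observed - lr@expected)
      # logrankTest's group 1 is the first factor level, i.e. grp == 0
      expect_equal(sum(mr[grp == 0]), oe,
                   tolerance = 1e-8 * max(1, abs(oe)))
    }
  }
})

test_that("survival-MDR cell labels coincide with residual-sum labels", {
  # per-cell log-rank O-E (cell vs rest) has the same sign as the cell's
  # residual sum under the no-covariate null fit, so both methods build
  # identical cell partitions
  set.seed(402)
  for (rep in 1:10) {
    n <- 150
    geno <- makeGeno(n, 2, seed = 500 + rep)
    evt <- rexp(n)
    cens <- runif(n, 0, 2)
    time <- pmin(evt, cens)
    status <- as.integer(evt <= cens)
    fit <- fitCoxNull(time, status)
    mr <- martingaleResiduals(fit, time, status)
    cells <- assignCells(geno, 1:2)
    labels <- labelCells(cells, mr)
    for (cell in which(labels != "EMPTY") - 1L) {
      inCell <- cells == cell
      if (all(inCell) || !any(inCell)) next
      lr <- logrankTest(time, status, ifelse(inCell, "cell", "rest"))
      oe <- sum(lr@observed - lr@expected)  # group 1 = "cell"
      expect_equal(unname(labels[cell + 1L]),
                   if (oe >= 0) "HIGH" else "LOW")
    }
  }
})
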