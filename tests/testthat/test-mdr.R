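test_that("cell assignment follows the row-major dosage convention", {
  g <- rbind(c(0L, 0L), c(1L, 2L), c(2L, 1L), c(NA_integer_, 1L))
  colnames(g) <- c("a", "b")
  expect_equal(as.integer(assignCells(g, 1L)), c(0L, 1L, 2L, NA))
  cells <- assignCells(g, 1:2)
  expect_equal(as.integer(cells), c(0L, 5L, 7L, NA))   # (2,1) -> 2*3+1
  expect_equal(attr(cells, "k"), 2L)
})

test_that("cell labeling applies the >= 0 high-risk rule", {
  cells <- structure(c(0L, 0L, 1L, 1L, 2L), k = 1L)
  lab <- labelCells(cells, c(0.3, -0.1, -0.2, -0.4, 0))
  expect_equal(unname(lab), c("HIGH", "LOW", "HIGH"))  # sum 0 -> HIGH
  lab2 <- labelCells(structure(c(0L, 2L), k = 1L), c(1, -1))
  expect_equal(unname(lab2), c("HIGH", "EMPTY", "LOW"))
  # prediction: trained labels carry over; untrained cells -> LOW without
  # residuals, cell-sum rule with them
  expect_equal(applyCellLabels(lab2, structure(0:2, k = 1L)),
               c("HIGH", "LOW", "LOW"))
  expect_equal(applyCellLabels(lab2, structure(0:2, k = 1L),
                               residuals = c(-5, 2, -5)),
               c("HIGH", "HIGH", "LOW"))
})

test_that("t score equals the textbook pooled t and honors conventions", {
  cells <- structure(c(rep(0L, 3), rep(2L, 3)), k = 1L)
  resid <- c(1, 1.2, 0.8, -1, -0.9, -1.1)
  lab <- labelCells(cells, resid)
  expect_equal(tScore(lab, cells, resid), oracleT(resid[1:3], resid[4:6]))
  expect_equal(tScore(lab, cells, resid, welch = TRUE),
               unname(t.test(resid[1:3], resid[4:6])$statistic))
  # one pooled group empty -> uninformative, score 0
  allHigh <- labelCells(cells, abs(resid))
  expect_equal(tScore(allHigh, cells, abs(resid)), 0)
  # zero pooled variance -> error
  const <- c(1, 1, 1, -1, -1, -1)
  expect_error(tScore(labelCells(cells, const), cells, const),
               "zero pooled variance")
})

test_that("the search enumerates exhaustively and is chunk-invariant", {
  sim <- simulateNull(m = 5, n = 120, seed = 21)
  res <- esmdrSearch(sim$genotype, sim$outcome, k = 1:2, seed = 22)
  expect_equal(sum(res@models$k == 1), 5)
  expect_equal(sum(res@models$k == 2), choose(5, 2))
  res2 <- esmdrSearch(sim$genotype, sim$outcome, k = 1:2, seed = 22,
                      chunkSize = 3L)
  expect_equal(res@models$testScore, res2@models$testScore)
  expect_equal(res@best$snps, res2@best$snps)
})

test_that("a noiseless single-SNP effect is found with full consistency", {
  g <- makeGeno(200, 8, seed = 23)
  outcome <- as.numeric(g[, 5] >= 1) * 2 - 1   # deterministic signal on SNP5
  res <- esmdrSearch(g, outcome, k = 1, seed = 24)
  best <- bestModel(res, k = 1)
  expect_equal(best$snps, "SNP5")
  expect_equal(best$cvConsistency, 2L)
  # brute force over per-SNP group-mean differences agrees
  diffs <- apply(g, 2, function(col) {
    hi <- outcome[col >= 1]; lo <- outcome[col < 1]
    abs(mean(hi) - mean(lo))
  })
  expect_equal(best$snps, names(which.max(diffs)))
})

test_that("fold partitions are disjoint, exhaustive and seed-reproducible", {
  n <- 100
  f1 <- esmdr:::withSeed(31, sample(rep_len(1:2, n)))
  f2 <- esmdr:::withSeed(31, sample(rep_len(1:2, n)))
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:2)
  expect_equal(sum(f1 == 1), 50)
  sim <- simulateNull(m = 6, n = n, seed = 32)
  r1 <- esmdrSearch(sim$genotype, sim$outcome, k = 1, seed = 33)
  r2 <- esmdrSearch(sim$genotype, sim$outcome, k = 1, seed = 33)
  expect_identical(r1@best$testScore, r2@best$testScore)
  expect_error(esmdrSearch(sim$genotype, sim$outcome, k = 1, folds = 1,
                           seed = 33), "folds")
})

test_that("missing genotypes exclude subjects per model only", {
  g <- makeGeno(80, 3, seed = 41)
  g[1:10, 2] <- NA
  sim <- withr::with_seed(42, rnorm(80))
  res <- esmdrSearch(g, sim, k = 1, seed = 43)
  expect_equal(res@models$nUsed[res@models$snps == "SNP2"], 70L)
  expect_equal(res@models$nUsed[res@models$snps == "SNP1"], 80L)
})

test_that("permutation p-values behave as the add-one estimator", {
  g <- makeGeno(150, 3, seed = 51)
  outcome <- as.numeric(g[, 1] >= 1) * 3 + withr::with_seed(52, rnorm(150, sd = 0.1))
  pt <- permutationTest(g, outcome, snps = 1L, nPerm = 99L, seed = 53)
  expect_equal(pt$p, 1 / 100)   # observed beats every permutation
  expect_error(permutationTest(g, outcome, snps = 1L, nPerm = 0L, seed = 53),
               "nPerm")
})

test_that("null thresholds follow the quantile definitions", {
  expect_equal(nullThreshold(mode = "normal"), qnorm(0.95))
  expect_equal(nullThreshold(1:100, mode = "empirical"),
               unname(quantile(1:100, 0.95, type = 7)))
  expect_error(nullThreshold(1:50, mode = "empirical"), "at least 100")
  z <- withr::with_seed(54, rnorm(10000))
  expect_lt(abs(nullThreshold(z, mode = "empirical") - 1.6449), 0.05)
})
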