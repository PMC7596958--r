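#' Multi-locus genotype cell machinery
#'
#' `assignCells` maps each subject to one of the \eqn{3^k} genotype
#' combinations of a k-SNP tuple, in row-major order with the first SNP of
#' the tuple as the most significant digit (so genotypes (2, 1) give cell
#' 2*3 + 1 = 7).  A subject missing any of the k genotypes is excluded from
#' this model only and gets cell `NA`.
#'
#' @param geno dosage matrix, subjects in rows.
#' @param snps integer vector of k SNP column indices.
#' @return integer vector of 0-based cell indices (with `NA` for excluded
#'   subjects) and attribute `k`.
#' @export
assignCells <- function(geno, snps) {
  k <- length(snps)
  stopifnot(k >= 1L, all(snps >= 1L), all(snps <= ncol(geno)))
  sub <- geno[, snps, drop = FALSE]
  cells <- as.integer(sub %*% 3^((k - 1):0))
  attr(cells, "k") <- k
  cells
}

#' @rdname assignCells
#' @description `labelCells` labels every cell from the sign of its summed
#'   residuals: `HIGH` when the sum is >= 0 (the subject-level "greater than
#'   or equal to 0" rule extended to cells), `LOW` when negative, `EMPTY`
#'   when unpopulated.
#' @param cells output of `assignCells`.
#' @param residuals continuous surrogate outcome per subject (martingale
#'   residuals, or the raw quantitative outcome).
#' @return character vector of length `3^k` with values `"HIGH"`, `"LOW"`,
#'   `"EMPTY"`, named by cell index.
#' @export
labelCells <- function(cells, residuals) {
  k <- attr(cells, "k")
  if (is.null(k)) k <- max(1L, ceiling(log(max(cells, na.rm = TRUE) + 1, 3)))
  nc <- 3L^k
  lab <- rep("EMPTY", nc)
  names(lab) <- as.character(seq_len(nc) - 1L)
  ok <- !is.na(cells)
  if (any(ok)) {
    sums <- rowsum(residuals[ok], cells[ok])
    lab[rownames(sums)] <- ifelse(sums[, 1] >= 0, "HIGH", "LOW")
  }
  lab
}

#' @rdname assignCells
#' @description `applyCellLabels` assigns each subject the trained label of
#'   its cell.  Subjects falling in a cell that was empty during training
#'   are classified, when `residuals` are supplied, by the cell-sum rule
#'   applied to the data at hand (the search engine's default fallback);
#'   without residuals they are conservatively assigned `LOW`.
#' @param labels trained cell labels from `labelCells`.
#' @export
applyCellLabels <- function(labels, cells, residuals = NULL) {
  out <- labels[cells + 1L]
  empty <- !is.na(out) & out == "EMPTY"
  if (is.null(residuals)) {
    out[empty] <- "LOW"
  } else if (any(empty)) {
    fallback <- labelCells(cells, residuals)
    out[empty] <- fallback[cells[empty] + 1L]
  }
  unname(out)
}

#' Pooled two-sample t score of an MDR labeling
#'
#' Pools all HIGH-labeled cells into one group and all LOW-labeled cells
#' into the other and returns the two-sample t statistic on the residuals
#' (sign: HIGH minus LOW), the QMDR scoring statistic.  If one pooled group
#' is empty the model is uninformative and scores 0.
#'
#' @param cellLabels labels from [labelCells()].
#' @param cells,residuals as in [labelCells()].
#' @param welch use the Welch (unequal-variance) form instead of the
#'   pooled-variance default.
#' @return the t statistic (a single number).
#' @export
tScore <- function(cellLabels, cells, residuals, welch = FALSE) {
  grp <- cellLabels[cells + 1L]
  hi <- residuals[!is.na(grp) & grp == "HIGH"]
  lo <- residuals[!is.na(grp) & grp == "LOW"]
  if (!length(hi) || !length(lo)) return(0)
  if (welch) {
    if (length(hi) < 2L || length(lo) < 2L) return(0)
    se2 <- stats::var(hi) / length(hi) + stats::var(lo) / length(lo)
    if (se2 <= 0) stop("zero pooled variance")
    return((mean(hi) - mean(lo)) / sqrt(se2))
  }
  df <- length(hi) + length(lo) - 2
  if (df <= 0) return(0)
  sp2 <- (sum((hi - mean(hi))^2) + sum((lo - mean(lo))^2)) / df
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(hi) - mean(lo)) / sqrt(sp2 * (1 / length(hi) + 1 / length(lo)))
}

# Shared engine behind esmdrSearch / survmdrSearch.
#
# For each fold f the model's cells are labeled on the other folds
# (training); the training score is computed there with those labels and
# the fold test statistic on the held-out fold-f subjects, whose labels
# are therefore fully out-of-sample (with two folds the training halves
# are disjoint, so all predicted values are mutually independent of their
# outcomes under the null).  A model's reported test score combines its
# per-fold statistics as sum/sqrt(folds): independent N(0,1) fold
# statistics combine to an N(0,1) reference (for Surv-MDR the signed
# per-fold log-rank statistics are combined the same way and squared, for
# a chi-square(1) reference).
#
# Selection within each order k follows classic MDR mechanics: the best
# model of each fold is the one maximizing that fold's training score;
# cross-validation consistency = number of folds agreeing; the chosen
# model has the highest consistency, ties broken by mean training score,
# then by model index.  The k-level cross-validated prediction statistic
# (`cvTestScore`) accumulates each fold winner's OWN held-out fold
# statistic, sum/sqrt(folds): each term is selected only through training
# data disjoint from its evaluation fold, so under the null the statistic
# keeps its N(0,1) (resp. chi-square(1)) reference up to the empty-cell
# fallback. Held-out subjects whose cell was empty in training default to
# the cell-sum sign rule applied to the held-out data (emptyCells =
# "cell"); "self" uses each subject's own residual sign, "low" sends them
# all to the low-risk pool. The fallback is what gives the higher-order
# scans their residual small-sample anticonservatism. Across orders the
# overall best model again has the largest consistency, ties broken by
# the prediction statistic: a higher-order superset of a true pair must
# win both folds to displace it, not merely edge its statistic.
mdrEngine <- function(geno, y, k, folds, seed, method = c("esmdr", "survmdr"),
                      time = NULL, status = NULL, welch = FALSE,
                      emptyCells = c("cell", "self", "low"),
                      chunkSize = 50000L) {
  method <- match.arg(method)
  emptyRule <- match(match.arg(emptyCells), c("low", "self", "cell")) - 1L
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  m <- ncol(geno)
  if (is.null(colnames(geno))) colnames(geno) <- paste0("SNP", seq_len(m))
  if (length(y) != n) stop("outcome must have one value per subject")
  if (folds < 2L) stop("folds must be >= 2")
  if (is.null(seed)) stop("an explicit seed is required")
  seed <- as.integer(seed)
  fold <- withSeed(seed, sample(rep_len(seq_len(folds), n)))

  mcode <- 0L
  timeOrder <- integer(0)
  if (method == "survmdr") {
    if (is.null(time) || is.null(status))
      stop("survmdr scoring needs time and status")
    st <- as.integer(status)
    for (f in seq_len(folds)) {
      if (sum(st[fold == f]) < 2L)
        stop("fewer than 2 events in a fold")
    }
    mcode <- 1L
    timeOrder <- order(time)
  } else {
    time <- numeric(0); status <- integer(0)
  }

  modelRows <- list()
  bestRows <- list()
  for (kk in sort(unique(as.integer(k)))) {
    if (kk < 1L || kk > m) stop("invalid interaction order k")
    combos <- utils::combn(m, kk) - 1L
    M <- ncol(combos)
    train <- matrix(NA_real_, M, folds)
    ftest <- matrix(NA_real_, M, folds)
    test <- numeric(M)
    nused <- integer(M)
    for (st0 in seq(1L, M, by = chunkSize)) {
      en <- min(st0 + chunkSize - 1L, M)
      res <- cpp_mdr_cv(geno, as.numeric(y), fold, folds,
                        combos[, st0:en, drop = FALSE], mcode, welch,
                        as.numeric(time), as.integer(status),
                        as.integer(timeOrder), emptyRule)
      train[st0:en, ] <- res$trainScore
      ftest[st0:en, ] <- res$foldTest
      test[st0:en] <- res$testScore
      nused[st0:en] <- res$nUsed
    }
    sel <- selectFromScan(train, ftest, method)
    meanTrain <- rowMeans(train)
    ids <- do.call(paste, c(lapply(seq_len(kk), function(j)
      colnames(geno)[combos[j, ] + 1L]), sep = ","))
    modelRows[[length(modelRows) + 1L]] <- S4Vectors::DataFrame(
      k = kk, snps = ids, cvConsistency = sel$consistency,
      meanTrainScore = meanTrain, testScore = test, nUsed = nused)
    bestRows[[length(bestRows) + 1L]] <- S4Vectors::DataFrame(
      k = kk, snps = ids[sel$chosen], cvConsistency = sel$consistency[sel$chosen],
      meanTrainScore = meanTrain[sel$chosen], testScore = test[sel$chosen],
      cvTestScore = sel$cvStat, nUsed = nused[sel$chosen])
  }
  models <- do.call(rbind, modelRows)
  best <- do.call(rbind, bestRows)
  # across orders: largest consistency first, then the prediction statistic
  overall <- order(-best$cvConsistency, -best$cvTestScore)[1L]
  methods::new("MDRResult", models = models, best = best,
               overallBest = as.integer(overall),
               method = method, folds = as.integer(folds), seed = seed,
               snpIds = colnames(geno), nSubjects = as.integer(n))
}

# Fold-winner bookkeeping shared by the full engine and the lean
# simulation scans: per-fold best model by training score, CV consistency,
# chosen model (consistency, then mean training score, then index) and the
# cross-validated prediction statistic accumulated from each fold winner's
# held-out fold statistic.
selectFromScan <- function(train, foldTest, method) {
  M <- nrow(train)
  folds <- ncol(train)
  foldBest <- apply(train, 2L, which.max)
  consistency <- tabulate(foldBest, nbins = M)
  meanTrain <- rowMeans(train)
  chosen <- order(-consistency, -meanTrain, seq_len(M))[1L]
  cvStat <- sum(foldTest[cbind(foldBest, seq_len(folds))]) / sqrt(folds)
  if (method == "survmdr") cvStat <- cvStat^2
  list(chosen = chosen, consistency = consistency, cvStat = cvStat,
       foldBest = foldBest)
}

# Lean per-dataset scan used by the simulation estimators: returns, per
# interaction order, the chosen model's SNP indices and the CV prediction
# statistic, without building result containers.  `combosList` caches the
# enumeration across replicates.
scanOnce <- function(geno, y, k, folds, seed, method = "esmdr",
                     time = NULL, status = NULL, combosList = NULL,
                     emptyRule = 2L) {
  n <- nrow(geno)
  fold <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  mcode <- if (method == "survmdr") 1L else 0L
  timeOrder <- if (mcode == 1L) order(time) else integer(0)
  if (mcode == 0L) { time <- numeric(0); status <- integer(0) }
  out <- vector("list", length(k))
  names(out) <- paste0(k, "-way")
  for (j in seq_along(k)) {
    combos <- if (!is.null(combosList)) combosList[[j]]
              else utils::combn(ncol(geno), k[j]) - 1L
    res <- cpp_mdr_cv(geno, as.numeric(y), fold, as.integer(folds), combos,
                      mcode, FALSE, as.numeric(time), as.integer(status),
                      as.integer(timeOrder), emptyRule)
    sel <- selectFromScan(res$trainScore, res$foldTest, method)
    out[[j]] <- list(snps = combos[, sel$chosen] + 1L, cvStat = sel$cvStat,
                     consistency = sel$consistency[sel$chosen])
  }
  out
}

#' Cross-validated exhaustive ES-MDR scan
#'
#' Runs the ES-MDR search: every k-tuple of SNPs is turned into a
#' \eqn{3^k}-cell contingency table, each cell is labeled high- or low-risk
#' by the sign of its summed martingale residuals on the training folds,
#' and the pooled HIGH-vs-LOW grouping is scored with the two-sample t
#' statistic.  The reported test score of a model combines the per-fold
#' out-of-sample t statistics as sum/\eqn{\sqrt{folds}} (an N(0,1)
#' reference under the null); models are selected by cross-validation
#' consistency with ties broken by mean training score.
#'
#' The exhaustive enumeration is processed in chunks of models; results are
#' identical regardless of the chunking.
#'
#' @param x dosage matrix (subjects in rows) or a
#'   [GenoSurvExperiment-class].  For a matrix, supply the continuous
#'   surrogate `outcome` (martingale residuals, or any quantitative
#'   outcome); for an experiment the covariate-adjusted martingale
#'   residuals are computed internally.
#' @param outcome continuous outcome per subject (matrix method).
#' @param k interaction orders to scan, e.g. `1:2` (orders above 3 are not
#'   supported by design).
#' @param folds number of cross-validation folds; the default two-fold
#'   split keeps the training halves disjoint.
#' @param seed required integer seed for the fold partition.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @param emptyCells handling of held-out subjects whose genotype cell was
#'   empty in training: `"cell"` (default) classifies the whole untrained
#'   cell by the sign of its own residual sum -- the cell-sum rule applied
#'   to the data at hand -- `"self"` classifies each such subject by the
#'   sign of its own residual, and `"low"` conservatively assigns them all
#'   to the low-risk pool.
#' @param chunkSize models per C++ call.
#' @return an [MDRResult-class].
#' @examples
#' sim <- simulateNull(m = 10, n = 100, seed = 1)
#' res <- esmdrSearch(sim$genotype, sim$outcome, k = 1:2, seed = 7)
#' bestModel(res)
#' @rdname esmdrSearch
#' @export
setMethod("esmdrSearch", "matrix",
          function(x, outcome, k = 1:2, folds = 2L, seed, welch = FALSE,
                   emptyCells = c("cell", "self", "low"),
                   chunkSize = 50000L) {
  if (any(k > 3L)) stop("interaction orders above 3 are not supported")
  mdrEngine(x, outcome, k = k, folds = folds, seed = seed, method = "esmdr",
            welch = welch, emptyCells = emptyCells, chunkSize = chunkSize)
})

#' @rdname esmdrSearch
#' @param ... passed to the matrix method.
#' @export
setMethod("esmdrSearch", "GenoSurvExperiment", function(x, k = 1:2, ...) {
  resid <- martingaleResiduals(x)
  esmdrSearch(genotypes(x), outcome = resid, k = k, ...)
})

#' Cross-validated exhaustive Surv-MDR scan
#'
#' The log-rank-based survival MDR baseline.  Cells are labeled by the sign
#' of the cell-vs-rest log-rank numerator, which equals the sign of the
#' summed covariate-free martingale residuals, so on identical data and
#' folds Surv-MDR and ES-MDR produce identical cell partitions; the score
#' differs: Surv-MDR uses the squared log-rank statistic between the pooled
#' HIGH and LOW groups.  Surv-MDR consumes time/status directly and offers
#' no covariate adjustment.
#'
#' @param x dosage matrix (subjects in rows) or [GenoSurvExperiment-class].
#' @param time,status survival outcome (matrix method).
#' @inheritParams esmdrSearch
#' @return an [MDRResult-class].
#' @rdname survmdrSearch
#' @export
setMethod("survmdrSearch", "matrix",
          function(x, time, status, k = 1:2, folds = 2L, seed,
                   emptyCells = c("cell", "self", "low"),
                   chunkSize = 50000L) {
  if (any(k > 3L)) stop("interaction orders above 3 are not supported")
  fit <- fitCoxNull(as.numeric(time), as.integer(status))
  resid <- martingaleResiduals(fit, time, status)
  mdrEngine(x, resid, k = k, folds = folds, seed = seed, method = "survmdr",
            time = time, status = status, emptyCells = emptyCells,
            chunkSize = chunkSize)
})

#' @rdname survmdrSearch
#' @param ... passed to the matrix method.
#' @export
setMethod("survmdrSearch", "GenoSurvExperiment", function(x, k = 1:2, ...) {
  survmdrSearch(genotypes(x), time = eventTime(x), status = eventStatus(x),
                k = k, ...)
})

#' @describeIn MDRResult-class the chosen model: the row of `best` for
#'   order `k`, or the overall best across orders when `k` is `NULL`.
#' @param k interaction order, or `NULL` for the overall best.
#' @export
setMethod("bestModel", "MDRResult", function(x, k = NULL) {
  if (is.null(k)) return(x@best[x@overallBest, , drop = FALSE])
  row <- which(x@best$k == k)
  if (!length(row)) stop("order k was not searched")
  x@best[row, , drop = FALSE]
})

#' @describeIn MDRResult-class the `n` top-ranked models of order `k`,
#'   ranked by test score (default) or by `"meanTrainScore"`.
#' @param n number of models.
#' @param by ranking column.
#' @export
setMethod("topModels", "MDRResult",
          function(x, k, n = 10L, by = c("testScore", "meanTrainScore")) {
  by <- match.arg(by)
  tab <- x@models[x@models$k == k, , drop = FALSE]
  if (!nrow(tab)) stop("order k was not searched")
  tab <- tab[order(-tab[[by]]), , drop = FALSE]
  utils::head(tab, n)
})

#' Permutation test for a chosen MDR model
#'
#' Permutes the surrogate outcome across subjects, recomputes the model's
#' cross-validated test statistic under each permutation (fold split held
#' fixed) and returns the add-one permutation p-value
#' \eqn{p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\}) / (1 + n_{perm})}.
#'
#' @param geno dosage matrix, subjects in rows.
#' @param outcome continuous surrogate outcome.
#' @param snps integer indices of the model's SNP tuple.
#' @param nPerm number of permutations (>= 1).
#' @param folds,seed cross-validation layout (the same seed reproduces the
#'   fold split used by the search).
#' @param welch as in [esmdrSearch()].
#' @return list with `p`, `observed` and the vector of permuted scores.
#' @export
permutationTest <- function(geno, outcome, snps, nPerm = 999L, folds = 2L,
                            seed, welch = FALSE) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  geno <- as.matrix(geno[, snps, drop = FALSE])
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  seed <- as.integer(seed)
  fold <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  combos <- matrix(seq_len(ncol(geno)) - 1L, ncol = 1L)
  score1 <- function(yy) {
    cpp_mdr_cv(geno, as.numeric(yy), fold, as.integer(folds), combos, 0L,
               welch, numeric(0), integer(0), integer(0), 2L)$testScore
  }
  obs <- score1(outcome)
  permSeeds <- deriveSeeds(seed + 1L, nPerm)
  perm <- vapply(permSeeds, function(s)
    score1(withSeed(s, sample(outcome))), 0)
  list(p = (1 + sum(perm >= obs)) / (1 + nPerm), observed = obs,
       permScores = perm)
}

#' Significance threshold for MDR test scores
#'
#' Either the empirical 95th percentile (type-7 interpolation) of a set of
#' null test scores, or, in `"normal"` mode, the corresponding quantile of
#' the standard normal reference distribution (1.6449 at level 0.95), which
#' the null distribution of the 1- and 2-way pooled test scores follows
#' closely.
#'
#' @param nullScores numeric vector of null-model test scores (>= 100
#'   values required in empirical mode).
#' @param mode `"empirical"` or `"normal"`.
#' @param level quantile level.
#' @return the threshold (a single number).
#' @export
nullThreshold <- function(nullScores = NULL,
                          mode = c("empirical", "normal"), level = 0.95) {
  mode <- match.arg(mode)
  if (mode == "normal") return(stats::qnorm(level))
  if (is.null(nullScores) || length(nullScores) < 100L)
    stop("empirical mode needs at least 100 null scores")
  unname(stats::quantile(nullScores, level, type = 7))
}
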