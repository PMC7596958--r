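#' Greedy LD pruning
#'
#' Single greedy pass in map order: a SNP is dropped when its squared
#' Pearson correlation with an already-retained SNP inside the window
#' exceeds `r2Max` (default 0.1, a stringent threshold leaving an
#' approximately independent marker set).  Monomorphic comparisons
#' (undefined correlation) never trigger a drop.
#'
#' @param geno dosage matrix, subjects in rows.
#' @param r2Max maximum allowed squared correlation, in (0, 1].
#' @param window number of map positions back to compare against
#'   (`Inf` compares with every retained SNP).
#' @return list with `keep` (retained column indices) and `genotype`
#'   (the pruned matrix).
#' @export
ldPrune <- function(geno, r2Max = 0.1, window = 100L) {
  stopifnot(r2Max > 0, r2Max <= 1)
  m <- ncol(geno)
  keep <- integer(0)
  for (j in seq_len(m)) {
    cand <- keep[keep > j - window]
    drop <- FALSE
    if (length(cand)) {
      r <- suppressWarnings(
        stats::cor(geno[, j], geno[, cand, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      drop <- any(r^2 > r2Max)
    }
    if (!drop) keep <- c(keep, j)
  }
  list(keep = keep, genotype = geno[, keep, drop = FALSE])
}

#' Seeded train/test split
#'
#' Disjoint, exhaustive partition of `n` subjects into a training set of
#' size `floor(ratio * n)` and a test set holding the remainder.
#'
#' @param n subject count (>= 3).
#' @param ratio training fraction (default 2/3).
#' @param seed required seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitTrainTest <- function(n, ratio = 2 / 3, seed) {
  stopifnot(n >= 3L, ratio > 0, ratio < 1)
  train <- withSeed(seed, sort(sample.int(n, floor(ratio * n))))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Pool the SNPs of the top-ranked models
#'
#' Takes the union of all SNP identifiers appearing in the `topM`
#' best-scoring models of each searched interaction order (ranked by test
#' score), deduplicated, keeping each SNP's best rank and score as
#' metadata.
#'
#' @param result an [MDRResult-class].
#' @param topM models per order to pool (default 1000).
#' @return data.frame with columns `snp`, `bestScore`, `bestRank`, `k`.
#' @export
poolTopSnps <- function(result, topM = 1000L) {
  stopifnot(is(result, "MDRResult"))
  rows <- list()
  for (kk in unique(result@models$k)) {
    tab <- topModels(result, k = kk, n = topM)
    for (i in seq_len(nrow(tab))) {
      for (s in strsplit(tab$snps[i], ",")[[1]]) {
        prev <- rows[[s]]
        if (is.null(prev) || tab$testScore[i] > prev$bestScore)
          rows[[s]] <- data.frame(snp = s, bestScore = tab$testScore[i],
                                  bestRank = i, k = kk)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$bestScore), , drop = FALSE]
}

#' Lasso-penalized Cox selection of predictive SNPs
#'
#' L1-penalized Cox partial-likelihood path over the candidate SNPs (via
#' glmnet), with the penalty chosen by cross-validated partial likelihood;
#' adjustment covariates such as smoking enter unpenalized.  Designed for
#' the p > n regime that the pooled top-model SNP set can produce.
#'
#' @param geno candidate SNP dosage matrix, subjects in rows.
#' @param time,status survival outcome.
#' @param covariates optional unpenalized covariates.
#' @param nfolds CV folds for the penalty path (default 10).
#' @param lambda `"lambda.min"` or `"lambda.1se"`, or a numeric penalty.
#' @param seed seed for the CV fold assignment.
#' @return list with `selected` (SNP names with nonzero coefficients),
#'   `coef` (all nonzero coefficients incl. covariates), `lambda` and the
#'   underlying `cv.glmnet` fit.
#' @export
lassoCoxSelect <- function(geno, time, status, covariates = NULL,
                           nfolds = 10L, lambda = "lambda.min", seed = 1L) {
  if (sum(status) < 1L) stop("no events")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  snpNames <- colnames(geno)
  x <- geno
  pf <- rep(1, ncol(geno))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    x <- cbind(x, cv)
    pf <- c(pf, rep(0, ncol(cv)))
  }
  y <- cbind(time = as.numeric(time), status = as.integer(status))
  if (is.character(lambda)) {
    foldid <- withSeed(seed, sample(rep_len(seq_len(nfolds), nrow(x))))
    fit <- glmnet::cv.glmnet(x, y, family = "cox", penalty.factor = pf,
                             foldid = foldid)
    lam <- fit[[lambda]]
    cf <- as.matrix(stats::coef(fit, s = lam))[, 1]
  } else {
    # a fixed penalty: solve at that lambda exactly (interpolating along a
    # cross-validation path would be inaccurate off-grid)
    lam <- lambda
    fit <- glmnet::glmnet(x, y, family = "cox", penalty.factor = pf,
                          lambda = sort(unique(c(lam * c(100, 10, 1))),
                                        decreasing = TRUE),
                          thresh = 1e-12)
    cf <- as.matrix(stats::coef(fit, s = lam))[, 1]
  }
  nz <- cf[cf != 0]
  list(selected = intersect(names(nz), snpNames), coef = nz, lambda = lam,
       fit = fit)
}

# Linear predictor of a lasso-Cox selection on (possibly new) data.
lassoRiskScore <- function(sel, geno, covariates = NULL) {
  x <- as.matrix(geno)
  if (!is.null(covariates)) x <- cbind(x, as.matrix(as.data.frame(covariates)))
  cf <- sel$coef
  miss <- setdiff(names(cf), colnames(x))
  if (length(miss)) stop("columns missing from scoring data: ",
                         paste(miss, collapse = ", "))
  drop(x[, names(cf), drop = FALSE] %*% cf)
}

#' Time-dependent ROC curve and AUC
#'
#' Cumulative-case / dynamic-control time-dependent ROC at horizon `t`
#' for a risk score f(X): sensitivity(c, t) = Pr(f(X) > c | event by t)
#' and specificity(c, t) = Pr(f(X) <= c | event-free at t), estimated with
#' the Kaplan-Meier-based estimator of Heagerty, Lumley and Pepe
#' (conditional KM within the score strata `{f(X) > c}` and
#' `{f(X) <= c}`, Bayes-combined with the marginal KM).  The AUC is the
#' trapezoidal area along the cutoff sweep.  The AUC is invariant to
#' strictly monotone transforms of the score because cutoffs run over the
#' observed score values.
#'
#' @param score risk score per subject (larger = higher risk).
#' @param time,status survival outcome.
#' @param predictTime evaluation horizon t (within the observed range).
#' @return list with `cutoffs`, `sens`, `fpr` (1 - specificity), `auc` and
#'   the horizon; if no events have occurred by t the ROC is undefined and
#'   `auc` is `NA` with a warning.
#' @export
tdROC <- function(score, time, status, predictTime) {
  n <- length(score)
  stopifnot(length(time) == n, length(status) == n)
  St <- kmAt(time, status, predictTime)
  if (St >= 1) {
    warning("no events by the requested horizon; ROC undefined")
    return(list(cutoffs = numeric(0), sens = numeric(0), fpr = numeric(0),
                auc = NA_real_, predictTime = predictTime))
  }
  cuts <- sort(unique(score), decreasing = TRUE)
  sens <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    c0 <- cuts[i]
    above <- score > c0
    pAbove <- mean(above)
    Sab <- if (any(above)) kmAt(time[above], status[above], predictTime) else 1
    Sbe <- if (any(!above)) kmAt(time[!above], status[!above], predictTime) else 1
    sens[i] <- (1 - Sab) * pAbove / (1 - St)
    fpr[i] <- 1 - Sbe * (1 - pAbove) / St
  }
  xs <- c(0, fpr, 1)
  ys <- c(0, sens, 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  list(cutoffs = cuts, sens = sens, fpr = fpr, auc = auc,
       predictTime = predictTime)
}

#' Kaplan-Meier risk-group stratification with adjusted hazard ratio
#'
#' Splits subjects by a trained HIGH/LOW MDR labeling, returns the
#' per-group product-limit curves and the hazard ratio of HIGH vs LOW from
#' a Cox model adjusted for the supplied covariates (e.g. smoking status).
#'
#' @param group character/factor of per-subject risk labels (`"HIGH"` /
#'   `"LOW"`, e.g. from [applyCellLabels()]).
#' @param time,status survival outcome.
#' @param covariates optional adjustment covariates.
#' @param conf confidence level for the HR interval.
#' @return list with `km` (curve data.frame), `hr`, `ci`, `p` (Wald) and
#'   the underlying [CoxNullFit-class].
#' @export
kmRiskGroups <- function(group, time, status, covariates = NULL,
                         conf = 0.95) {
  group <- as.character(group)
  if (length(unique(group)) != 2L || !all(group %in% c("HIGH", "LOW")))
    stop("need both HIGH and LOW groups")
  km <- kmCurve(time, status, group)
  X <- data.frame(high = as.numeric(group == "HIGH"))
  if (!is.null(covariates)) X <- cbind(X, as.data.frame(covariates))
  fit <- fitCoxNull(as.numeric(time), as.integer(status), covariates = X)
  b <- coef(fit)["high"]
  se <- sqrt(diag(vcov(fit)))[1]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(km = km, hr = unname(exp(b)),
       ci = unname(exp(c(b - z * se, b + z * se))),
       p = unname(2 * stats::pnorm(-abs(b / se))), fit = fit)
}

#' End-to-end prediction pipeline
#'
#' The applied analysis chain: LD pruning, a seeded 2/3-1/3 train/test
#' split, covariate-adjusted martingale residuals on the training set, an
#' exhaustive 1-/2-way ES-MDR scan, pooling of the SNPs in the top-ranked
#' models, lasso-Cox selection (covariates unpenalized), and evaluation on
#' the held-out third: time-dependent AUC over a horizon sweep and KM risk
#' stratification by the best model's labeling.
#'
#' Besides the pooled SNP dosages, the lasso design matrix carries the
#' trained HIGH/LOW risk attribute of the `nInteractions` top-ranked
#' two-way models (one binary column per model, named `"SNPa:SNPb"`).  A
#' purely epistatic pair has no marginal dosage effect, so without its
#' risk attribute no additive selection step could retain it; selecting
#' the attribute reports both member SNPs.
#'
#' @param gse a [GenoSurvExperiment-class] with `time`, `status` and
#'   covariates in `colData`.
#' @param k interaction orders to scan (default 1:2).
#' @param r2Max,window LD pruning controls.
#' @param ratio training fraction.
#' @param topM models pooled per order.
#' @param nInteractions top two-way models whose risk attribute joins the
#'   lasso design matrix.
#' @param aucTimes horizons for the AUC sweep (default: quartiles of the
#'   observed event times in the test set).
#' @param seed seed driving every stochastic step.
#' @return list with elements `prune`, `split`, `search`, `pooled`,
#'   `lasso`, `selectedSnps` (SNPs named by the selected features, pair
#'   attributes expanded to their member SNPs), `auc` (data.frame
#'   time/auc), `km` and `config`.
#' @export
runPredictionPipeline <- function(gse, k = 1:2, r2Max = 0.1, window = 100L,
                                  ratio = 2 / 3, topM = 1000L,
                                  nInteractions = 10L, aucTimes = NULL,
                                  seed = 1L) {
  stopifnot(is(gse, "GenoSurvExperiment"))
  geno <- genotypes(gse)
  tm <- eventTime(gse)
  st <- eventStatus(gse)
  covs <- covariateMatrix(gse)
  seeds <- deriveSeeds(seed, 4L)

  pr <- ldPrune(geno, r2Max = r2Max, window = window)
  sp <- splitTrainTest(nrow(geno), ratio = ratio, seed = seeds[1])
  trG <- pr$genotype[sp$train, , drop = FALSE]
  teG <- pr$genotype[sp$test, , drop = FALSE]
  trCov <- if (is.null(covs)) NULL else covs[sp$train, , drop = FALSE]
  teCov <- if (is.null(covs)) NULL else covs[sp$test, , drop = FALSE]

  fit <- fitCoxNull(tm[sp$train], st[sp$train], covariates = trCov)
  resid <- martingaleResiduals(fit, tm[sp$train], st[sp$train],
                               covariates = trCov)
  search <- esmdrSearch(trG, outcome = resid, k = k, seed = seeds[2])
  pooled <- poolTopSnps(search, topM = topM)

  trX <- trG[, pooled$snp, drop = FALSE]
  teX <- teG[, pooled$snp, drop = FALSE]
  if (nInteractions > 0L && 2L %in% search@models$k) {
    tp <- topModels(search, k = 2L, n = nInteractions)
    for (i in seq_len(nrow(tp))) {
      idx <- match(strsplit(tp$snps[i], ",")[[1]], colnames(pr$genotype))
      trCells <- assignCells(trG, idx)
      labs <- labelCells(trCells, resid)
      nm <- gsub(",", ":", tp$snps[i])
      # prediction-time labeling is outcome-free: untrained cells -> LOW
      trF <- as.numeric(applyCellLabels(labs, trCells) == "HIGH")
      teF <- as.numeric(applyCellLabels(labs, assignCells(teG, idx)) == "HIGH")
      trX <- cbind(trX, trF); colnames(trX)[ncol(trX)] <- nm
      teX <- cbind(teX, teF); colnames(teX)[ncol(teX)] <- nm
    }
  }
  lasso <- lassoCoxSelect(trX, tm[sp$train], st[sp$train],
                          covariates = trCov, seed = seeds[3])
  selectedSnps <- unique(unlist(strsplit(lasso$selected, ":")))

  testScore <- lassoRiskScore(lasso, teX, covariates = teCov)
  if (is.null(aucTimes)) {
    evTimes <- tm[sp$test][st[sp$test] == 1]
    aucTimes <- unname(stats::quantile(evTimes, c(0.25, 0.5, 0.75)))
  }
  auc <- data.frame(time = aucTimes,
                    auc = vapply(aucTimes, function(t0)
                      tdROC(testScore, tm[sp$test], st[sp$test], t0)$auc, 0))

  # KM stratification by the best model, trained on the training set and
  # applied to the held-out subjects
  bm <- bestModel(search)
  bmIdx <- match(strsplit(bm$snps, ",")[[1]], colnames(pr$genotype))
  trCells <- assignCells(trG, bmIdx)
  labels <- labelCells(trCells, resid)
  teLabels <- applyCellLabels(labels, assignCells(teG, bmIdx))
  km <- if (length(unique(teLabels)) == 2L)
    kmRiskGroups(teLabels, tm[sp$test], st[sp$test], covariates = teCov)
  else NULL

  list(prune = pr, split = sp, search = search, pooled = pooled,
       lasso = lasso, selectedSnps = selectedSnps, auc = auc, km = km,
       config = list(k = k, r2Max = r2Max, window = window, ratio = ratio,
                     topM = topM, nInteractions = nInteractions,
                     seed = seed, seeds = seeds))
}
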