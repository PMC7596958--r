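#' Simulate a null GWAS dataset
#'
#' Independent, non-interacting SNPs with minor allele frequencies drawn
#' from U(0.1, 0.5) (genotypes Binomial(2, MAF)), and standard-normal
#' continuous outcomes generated independently of the genotypes.  The
#' outcome feeds the MDR scorer directly as the continuous surrogate; no
#' survival layer is involved in the null study.
#'
#' @param m number of SNPs.
#' @param n number of subjects.
#' @param seed optional seed (the caller's RNG stream is restored).
#' @return list with `genotype` (n x m dosage matrix), `outcome` (length-n
#'   N(0,1) vector) and `maf` (the drawn frequencies).
#' @export
simulateNull <- function(m = 20L, n = 400L, seed = NULL) {
  withSeed(seed, {
    maf <- stats::runif(m, 0.1, 0.5)
    geno <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
    colnames(geno) <- paste0("SNP", seq_len(m))
    list(genotype = geno, outcome = stats::rnorm(n), maf = maf)
  })
}

#' Generate a purely epistatic two-locus penetrance table
#'
#' Constrained search (in the GAMETES spirit) over 3x3 tables
#' \eqn{f_{ij}} under Hardy-Weinberg genotype weights.  A random deviation
#' table is driven through alternating projections: onto the subspace
#' where both weighted marginals vanish (no main effects at either locus),
#' then rescaled so the broad-sense heritability
#' \eqn{h^2 = \sum_{ij} p_i q_j (f_{ij} - K)^2 / (K(1-K))}
#' matches the target, then clipped to the probability box [0, 1];
#' the cycle repeats until all three constraint sets are satisfied
#' simultaneously (to the class tolerances) or the start is abandoned
#' and redrawn.
#'
#' Not every (maf, h2, K) combination is geometrically feasible: at
#' maf = 0.2 no prevalence supports h2 much above ~0.43, and K = 0.5
#' caps it near 0.3.  When `prevalence` is `NULL` (default) the generator
#' therefore searches a prevalence grid from 0.5 downward and returns the
#' first table found, recording the prevalence used in the object.
#'
#' @param maf shared minor allele frequency of the two functional SNPs,
#'   in (0, 0.5].
#' @param h2 target broad-sense heritability, in (0, 1).
#' @param prevalence marginal probability K of the high-risk state, or
#'   `NULL` to search the default grid 0.5, 0.45, ..., 0.25.
#' @param seed optional seed.
#' @param maxTries random restarts per prevalence before giving up.
#' @return a [PenetranceModel-class].
#' @examples
#' pm <- makePenetrance(0.4, 0.2, seed = 1)
#' pm
#' @export
makePenetrance <- function(maf, h2, prevalence = NULL, seed = NULL,
                           maxTries = 60L) {
  stopifnot(maf > 0, maf <= 0.5, h2 > 0, h2 < 1)
  Kgrid <- if (is.null(prevalence)) seq(0.5, 0.25, by = -0.05)
           else prevalence
  stopifnot(all(Kgrid > 0 & Kgrid < 1))
  w <- hweWeights(maf)
  ww <- outer(w, w)
  project <- function(d) {
    for (it in 1:200) {
      d <- d - drop(d %*% w)                  # row-center
      d <- d - rep(drop(w %*% d), each = 3)   # column-center
      if (max(abs(d %*% w), abs(w %*% d)) < 1e-12) break
    }
    d
  }
  withSeed(seed, {
    for (K in Kgrid) {
      target <- h2 * K * (1 - K)
      for (try in seq_len(maxTries)) {
        d <- project(matrix(stats::rnorm(9), 3, 3) * sqrt(ww))
        ok <- FALSE
        for (cycle in 1:120) {
          s2 <- sum(ww * d^2)
          if (s2 < 1e-14) break
          d <- d * sqrt(target / s2)          # hit the heritability
          f <- K + d
          if (all(f >= -1e-12 & f <= 1 + 1e-12)) { ok <- TRUE; break }
          d <- project(pmin(pmax(f, 0), 1) - K)  # clip, restore marginals
        }
        if (!ok) next
        f <- pmin(pmax(K + d, 0), 1)
        h2ach <- sum(ww * (f - K)^2) / (K * (1 - K))
        marg <- max(abs(f %*% w - K), abs(w %*% f - K))
        if (abs(h2ach - h2) <= 0.05 * h2 && marg <= 1e-3) {
          return(methods::new("PenetranceModel", f = f, maf = maf,
                              h2target = h2, h2 = h2ach, prevalence = K))
        }
      }
    }
    stop(sprintf("no valid penetrance table found for maf=%.2f, h2=%.3f",
                 maf, h2))
  })
}

#' Simulate epistatic survival data from a penetrance model
#'
#' Two functional SNPs are drawn under Hardy-Weinberg equilibrium and the
#' latent high-risk state is Bernoulli with probability \eqn{f_{ij}};
#' subjects are rejection-sampled until the design holds exactly n/2
#' high-risk and n/2 low-risk subjects.  Event times follow a Weibull
#' baseline (shape 5, scale 2) proportional-hazards model with hazard
#' multiplied by \eqn{e^{\beta x}}, where x is the risk indicator (1 =
#' high risk); censoring times are uniform on (0, `censorMax`), observed
#' time = min(T, C) and status = 1(T <= C).  At the default `beta = 1.5`
#' the design censors about 40% of subjects.  Independent noise SNPs with
#' MAF ~ U(0.1, 0.5) are appended.
#'
#' @param pm a [PenetranceModel-class].
#' @param n total subjects (split evenly between risk classes).
#' @param beta log hazard ratio of the high-risk class.
#' @param shape,scale Weibull baseline parameters.
#' @param censorMax upper limit of the uniform censoring distribution.
#' @param nNoise number of non-functional SNPs appended (columns 3 onward).
#' @param seed optional seed.
#' @return a [GenoSurvExperiment-class]; the functional loci are columns
#'   `SNP1`/`SNP2` (flagged in `rowData(x)$functional`) and the latent risk
#'   class is kept in `S4Vectors::metadata(x)$riskClass`.
#' @export
simulateEpistatic <- function(pm, n = 400L, beta = 1.5, shape = 5,
                              scale = 2, censorMax = 4, nNoise = 18L,
                              seed = NULL) {
  stopifnot(is(pm, "PenetranceModel"), n >= 4L)
  nHigh <- n %/% 2L
  nLow <- n - nHigh
  w <- hweWeights(pm@maf)
  withSeed(seed, {
    gHigh <- matrix(0L, 0, 2)
    gLow <- matrix(0L, 0, 2)
    while (nrow(gHigh) < nHigh || nrow(gLow) < nLow) {
      b <- max(2L * n, 512L)
      g1 <- sample(0:2, b, replace = TRUE, prob = w)
      g2 <- sample(0:2, b, replace = TRUE, prob = w)
      risk <- stats::rbinom(b, 1L, pm@f[cbind(g1 + 1L, g2 + 1L)])
      gHigh <- rbind(gHigh, cbind(g1, g2)[risk == 1L, , drop = FALSE])
      gLow <- rbind(gLow, cbind(g1, g2)[risk == 0L, , drop = FALSE])
    }
    func <- rbind(gHigh[seq_len(nHigh), , drop = FALSE],
                  gLow[seq_len(nLow), , drop = FALSE])
    x <- rep(c(1L, 0L), c(nHigh, nLow))
    # Weibull PH: S(t|x) = exp(-(t/scale)^shape * exp(beta x))
    evt <- scale * (stats::rexp(n) / exp(beta * x))^(1 / shape)
    cens <- stats::runif(n, 0, censorMax)
    time <- pmin(evt, cens)
    status <- as.integer(evt <= cens)
    mafNoise <- stats::runif(nNoise, 0.1, 0.5)
    noise <- vapply(mafNoise, function(p) stats::rbinom(n, 2L, p),
                    integer(n))
    geno <- cbind(func, noise)
    colnames(geno) <- paste0("SNP", seq_len(ncol(geno)))
    gse <- GenoSurvExperiment(geno, time = time, status = status,
                              snpInfo = data.frame(
                                functional = seq_len(ncol(geno)) <= 2L,
                                trueMAF = c(pm@maf, pm@maf, mafNoise)))
    # simulation truth lives in metadata, not colData: colData covariate
    # columns enter the Cox null fit
    S4Vectors::metadata(gse)$riskClass <- x
    gse
  })
}

#' Type-I error of the cross-validated MDR scan under the null
#'
#' Repeatedly simulates null datasets ([simulateNull()]), runs the ES-MDR
#' scan and records, for each interaction order, whether the chosen
#' model's cross-validated test score exceeds the significance threshold
#' (by default the 95th standard-normal quantile, 1.6449).  The returned
#' rates estimate the fraction of null datasets in which the scan
#' "identifies" an interaction.
#'
#' @param m,n dataset dimensions.
#' @param reps number of null replicates (>= 100 recommended).
#' @param k interaction orders to scan.
#' @param thresholdMode `"normal"` (default) or `"empirical"` (95th
#'   percentile of the replicate scores themselves).
#' @param level threshold level.
#' @param folds cross-validation folds.
#' @param seed seed for the whole experiment.
#' @return data.frame with columns `k` and `rate` (in percent); the matrix
#'   of per-replicate chosen-model test scores is attached as attribute
#'   `"scores"` (reps x length(k)).
#' @export
estimateTypeIError <- function(m = 20L, n = 400L, reps = 1000L, k = 1:3,
                               thresholdMode = c("normal", "empirical"),
                               level = 0.95, folds = 2L, seed = 1L) {
  thresholdMode <- match.arg(thresholdMode)
  k <- sort(unique(as.integer(k)))
  seeds <- deriveSeeds(seed, 2L * reps)
  combosList <- lapply(k, function(kk) utils::combn(m, kk) - 1L)
  scores <- matrix(NA_real_, reps, length(k),
                   dimnames = list(NULL, paste0(k, "-way")))
  for (r in seq_len(reps)) {
    dat <- simulateNull(m, n, seed = seeds[r])
    res <- scanOnce(dat$genotype, dat$outcome, k = k, folds = folds,
                    seed = seeds[reps + r], combosList = combosList)
    scores[r, ] <- vapply(res, `[[`, 0, "cvStat")
  }
  thr <- if (thresholdMode == "normal") stats::qnorm(level)
         else apply(scores, 2L, function(s) nullThreshold(s, "empirical", level))
  rates <- 100 * colMeans(sweep(scores, 2L, thr, `>`))
  out <- data.frame(k = k, rate = unname(rates))
  attr(out, "scores") <- scores
  attr(out, "threshold") <- thr
  out
}

#' Power of ES-MDR and Surv-MDR on purely epistatic survival data
#'
#' For each replicate a fresh penetrance table is generated at the
#' requested (maf, h2), balanced epistatic survival data are simulated,
#' and both methods scan all 1-, 2- and 3-way models over the 2 functional
#' plus `nNoise` noise SNPs (sharing the same genotypes and fold split).
#' A replicate counts as a success when the overall best model contains
#' the functional pair -- exactly (`stringent`) or allowing one extra SNP
#' in a 3-way model (`flexible`) -- and its test score clears the 0.05
#' significance threshold (standard-normal 95th quantile for the ES-MDR t
#' score; the chi-square(1) 95th quantile for the Surv-MDR squared
#' log-rank score).
#'
#' @param maf,h2 penetrance model parameters (see [makePenetrance()]).
#' @param n subjects per dataset.
#' @param reps replicates.
#' @param beta,prevalence,nNoise generator settings
#'   (see [simulateEpistatic()]).
#' @param method `"both"`, `"esmdr"` or `"survmdr"`.
#' @param folds,seed cross-validation layout.
#' @return data.frame with one row per (method, mode): `power` in [0, 1]
#'   plus its binomial Monte-Carlo standard error.
#' @export
estimatePower <- function(maf, h2, n = 400L, reps = 100L, beta = 1.5,
                          prevalence = NULL, nNoise = 18L,
                          method = c("both", "esmdr", "survmdr"),
                          folds = 2L, seed = 1L) {
  method <- match.arg(method)
  doES <- method %in% c("both", "esmdr")
  doSM <- method %in% c("both", "survmdr")
  seeds <- deriveSeeds(seed, 3L * reps)
  thrES <- stats::qnorm(0.95)
  thrSM <- stats::qchisq(0.95, 1)
  kset <- 1:3
  combosList <- lapply(kset, function(kk) utils::combn(2L + nNoise, kk) - 1L)
  hit <- list(esmdr = matrix(FALSE, reps, 2), survmdr = matrix(FALSE, reps, 2))
  for (r in seq_len(reps)) {
    pm <- makePenetrance(maf, h2, prevalence, seed = seeds[r])
    gse <- simulateEpistatic(pm, n = n, beta = beta, nNoise = nNoise,
                             seed = seeds[reps + r])
    geno <- genotypes(gse)
    tm <- eventTime(gse)
    st <- eventStatus(gse)
    resid <- martingaleResiduals(fitCoxNull(tm, st), tm, st)
    # same genotypes, outcome-labeling residuals and fold split for both
    # methods: only the scoring statistic differs
    if (doES) {
      sc <- scanOnce(geno, resid, k = kset, folds = folds,
                     seed = seeds[2L * reps + r], combosList = combosList)
      hit$esmdr[r, ] <- successModes(sc, thrES)
    }
    if (doSM) {
      sc <- scanOnce(geno, resid, k = kset, folds = folds,
                     seed = seeds[2L * reps + r], method = "survmdr",
                     time = tm, status = st, combosList = combosList)
      hit$survmdr[r, ] <- successModes(sc, thrSM)
    }
  }
  rows <- list()
  for (mth in c("esmdr", "survmdr")) {
    if ((mth == "esmdr" && !doES) || (mth == "survmdr" && !doSM)) next
    pw <- colMeans(hit[[mth]])
    rows[[mth]] <- data.frame(method = mth,
                              mode = c("stringent", "flexible"),
                              power = pw, mcse = sqrt(pw * (1 - pw) / reps))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Success indicators (stringent, flexible) for the overall best model of a
# power-simulation scan (output of scanOnce): the functional loci occupy
# genotype columns 1 and 2.
successModes <- function(sc, threshold) {
  stats <- vapply(sc, `[[`, 0, "cvStat")
  cons <- vapply(sc, `[[`, 0L, "consistency")
  best <- sc[[order(-cons, -stats)[1L]]]
  sig <- best$cvStat > threshold
  both <- all(c(1L, 2L) %in% best$snps)
  c(stringent = sig && both && length(best$snps) == 2L,
    flexible = sig && both && length(best$snps) <= 3L)
}

#' Simulate a GWAS-scale-down scenario with planted signals
#'
#' Builds an m-SNP, n-subject survival dataset for exercising the full
#' prediction pipeline: one planted additive one-way signal, one planted
#' purely epistatic SNP pair (penetrance-driven risk class with no
#' marginal effects), optional blocks of correlated markers so LD pruning
#' has work to do, a binary smoking-type covariate with its own hazard
#' effect, and independent noise SNPs.  Event times follow the
#' Weibull(shape 5, scale 2) proportional-hazards baseline with uniform
#' censoring on (0, `censorMax`).
#'
#' @param m total SNPs.
#' @param n subjects.
#' @param mainSnp,pairSnps column positions of the planted signals.
#' @param mainBeta per-allele log hazard ratio of the one-way signal.
#' @param pairBeta log hazard ratio of the epistatic high-risk class.
#' @param pairMaf,pairH2 penetrance parameters of the planted pair.
#' @param ldBlocks number of 3-SNP correlated blocks among the noise SNPs.
#' @param covBeta log hazard ratio of the binary covariate.
#' @param censorMax upper uniform censoring limit.
#' @param seed optional seed.
#' @return a [GenoSurvExperiment-class] with `rowData(x)$planted` marking
#'   the functional columns.
#' @export
simulateGwasScenario <- function(m = 200L, n = 2000L, mainSnp = 10L,
                                 pairSnps = c(50L, 120L), mainBeta = 0.35,
                                 pairBeta = 1.5, pairMaf = 0.3,
                                 pairH2 = 0.25, ldBlocks = 10L,
                                 covBeta = 0.5, censorMax = 4, seed = NULL) {
  stopifnot(m >= 10L, !mainSnp %in% pairSnps)
  pm <- makePenetrance(pairMaf, pairH2, seed = seed)
  withSeed(seed, {
    maf <- stats::runif(m, 0.1, 0.5)
    geno <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
    w <- hweWeights(pairMaf)
    for (j in pairSnps)
      geno[, j] <- sample(0:2, n, replace = TRUE, prob = w)
    # correlated blocks: copy a parent SNP with 10% per-subject scrambling
    free <- setdiff(seq_len(m), c(mainSnp, pairSnps))
    blockParents <- free[seq_len(min(ldBlocks, length(free) %/% 3))]
    for (bp in blockParents) {
      kids <- setdiff(free, blockParents)[1:2]
      free <- setdiff(free, kids)
      for (kid in kids) {
        flip <- stats::runif(n) < 0.1
        geno[, kid] <- ifelse(flip, stats::rbinom(n, 2L, maf[bp]),
                              geno[, bp])
      }
    }
    smoking <- stats::rbinom(n, 1L, 0.45)
    risk <- stats::rbinom(n, 1L,
                          pm@f[cbind(geno[, pairSnps[1]] + 1L,
                                     geno[, pairSnps[2]] + 1L)])
    eta <- mainBeta * geno[, mainSnp] + pairBeta * risk + covBeta * smoking
    evt <- 2 * (stats::rexp(n) / exp(eta))^(1 / 5)
    cens <- stats::runif(n, 0, censorMax)
    colnames(geno) <- paste0("SNP", seq_len(m))
    gse <- GenoSurvExperiment(geno, time = pmin(evt, cens),
                              status = as.integer(evt <= cens),
                              covariates = data.frame(smoking = smoking),
                              snpInfo = data.frame(
                                planted = seq_len(m) %in% c(mainSnp, pairSnps)))
    S4Vectors::metadata(gse)$riskClass <- risk
    gse
  })
}
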