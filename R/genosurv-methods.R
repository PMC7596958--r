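#' @describeIn GenoSurvExperiment-class genotype dosage matrix with subjects
#'   in rows and SNPs in columns (transposed back from the internal assay).
#' @export
setMethod("genotypes", "GenoSurvExperiment", function(x) {
  t(SummarizedExperiment::assay(x, "genotype"))
})

#' @describeIn GenoSurvExperiment-class per-subject event/censoring times.
#' @export
setMethod("eventTime", "GenoSurvExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"time" %in% colnames(cd)) stop("no 'time' column in colData")
  cd$time
})

#' @describeIn GenoSurvExperiment-class per-subject event indicators.
#' @export
setMethod("eventStatus", "GenoSurvExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"status" %in% colnames(cd)) stop("no 'status' column in colData")
  cd$status
})

#' @describeIn GenoSurvExperiment-class covariate columns of `colData`
#'   (everything except `time` and `status`) as a numeric matrix, or `NULL`
#'   when there are none.
#' @export
setMethod("covariateMatrix", "GenoSurvExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  keep <- setdiff(colnames(cd), c("time", "status"))
  if (!length(keep)) return(NULL)
  as.matrix(as.data.frame(cd[, keep, drop = FALSE]))
})

#' @describeIn GenoSurvExperiment-class minor allele frequency per SNP,
#'   recomputed from the non-missing dosages and folded into [0, 0.5].
#' @export
setMethod("snpMAF", "GenoSurvExperiment", function(x) {
  g <- SummarizedExperiment::assay(x, "genotype")
  p <- rowMeans(g, na.rm = TRUE) / 2
  pmin(p, 1 - p)
})

setMethod("show", "GenoSurvExperiment", function(object) {
  cat(sprintf("GenoSurvExperiment: %d SNPs x %d subjects\n",
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  if ("status" %in% colnames(cd))
    cat(sprintf("  events: %d / %d (%.1f%% censored)\n",
                sum(cd$status == 1), ncol(object),
                100 * mean(cd$status == 0)))
  covs <- setdiff(colnames(cd), c("time", "status"))
  if (length(covs)) cat("  covariates:", paste(covs, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "CoxNullFit", function(object) {
  cat(sprintf("CoxNullFit: n = %d, events = %d, loglik = %.4f (%d iterations)\n",
              object@n, object@nevent, object@loglik, object@iterations))
  if (length(object@coefficients)) {
    se <- sqrt(diag(object@vcov))
    print(data.frame(coef = object@coefficients,
                     `exp(coef)` = exp(object@coefficients), se = se,
                     check.names = FALSE))
  } else {
    cat("  (no covariates; baseline is the Nelson-Aalen estimator)\n")
  }
  invisible(object)
})

#' @export
setMethod("coef", "CoxNullFit", function(object) object@coefficients)

#' @export
setMethod("vcov", "CoxNullFit", function(object) object@vcov)

setMethod("show", "LogRankResult", function(object) {
  cat(sprintf("Log-rank: O-E = %.4f, V = %.4f, C = %.4f (chisq = %.4f)\n",
              sum(object@observed - object@expected), object@variance,
              object@statistic, object@chisq))
  invisible(object)
})

setMethod("show", "PenetranceModel", function(object) {
  cat(sprintf(
    "PenetranceModel: maf = %.2f, K = %.2f, h2 = %.4f (target %.2g)\n",
    object@maf, object@prevalence, object@h2, object@h2target))
  f <- round(object@f, 3)
  dimnames(f) <- list(paste0("SNP1=", 0:2), paste0("SNP2=", 0:2))
  print(f)
  invisible(object)
})

setMethod("show", "MDRResult", function(object) {
  cat(sprintf("MDRResult (%s): %d models over %d SNPs, %d-fold CV, seed %d\n",
              object@method, nrow(object@models), length(object@snpIds),
              object@folds, object@seed))
  b <- as.data.frame(object@best)
  cat("Chosen model per interaction order:\n")
  print(b, row.names = FALSE)
  cat(sprintf("Overall best: %s (test score %.3f)\n",
              b$snps[object@overallBest], b$testScore[object@overallBest]))
  invisible(object)
})

# Hardy-Weinberg genotype frequencies (dosage 0/1/2) for a given MAF.
hweWeights <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# Run expr with a private RNG state seeded by `seed`, restoring the caller's
# stream afterwards. seed = NULL uses the ambient stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw sub-seeds (< 2^31) from a stream derived from `seed`.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
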