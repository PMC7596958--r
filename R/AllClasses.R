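#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @useDynLib esmdr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Container for genotypes with a censored age-of-onset phenotype
#'
#' `GenoSurvExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"genotype"`
#' assay holding additive minor-allele dosages (0, 1, 2, or `NA` for a
#' missing call) with SNPs in rows and subjects in columns.  The subject
#' phenotype lives in `colData`: an `time` column (age at event or at
#' censoring, in years), a `status` column (1 = event, 0 = censored) and any
#' number of covariate columns (e.g. smoking status).  Under the age-of-onset
#' coding, cases contribute an event at diagnosis age and controls are
#' censored at interview age.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [GenoSurvExperiment()] for the user-facing constructor,
#'   [genotypes()], [eventTime()], [eventStatus()], [covariateMatrix()],
#'   [snpMAF()].
#' @export
setClass("GenoSurvExperiment", contains = "SummarizedExperiment")

setValidity("GenoSurvExperiment", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  else {
    g <- SummarizedExperiment::assay(object, "genotype")
    bad <- !(g %in% c(0L, 1L, 2L)) & !is.na(g)
    if (any(bad))
      msg <- c(msg, "genotype entries must be 0, 1, 2 or NA")
  }
  cd <- SummarizedExperiment::colData(object)
  if ("time" %in% colnames(cd)) {
    tm <- cd$time
    if (any(!is.na(tm) & tm < 0))
      msg <- c(msg, "event/censoring times must be nonnegative")
  }
  if ("status" %in% colnames(cd)) {
    st <- cd$status
    if (any(!is.na(st) & !(st %in% c(0L, 1L))))
      msg <- c(msg, "status must be 0 (censored) or 1 (event)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenoSurvExperiment
#'
#' @param genotype numeric/integer matrix of additive dosages with
#'   *subjects in rows and SNPs in columns* (the usual GWAS orientation;
#'   it is transposed into the feature-by-sample assay internally).
#'   Entries must be 0, 1, 2 or `NA`.
#' @param time,status optional survival outcome per subject; `status` uses
#'   1 = event, 0 = censored.
#' @param covariates optional data.frame/matrix of per-subject covariates.
#' @param snpInfo optional per-SNP metadata (data.frame with one row per SNP).
#' @return a [GenoSurvExperiment-class] object.
#' @examples
#' g <- matrix(rbinom(40, 2, 0.3), nrow = 10,
#'             dimnames = list(NULL, paste0("rs", 1:4)))
#' gse <- GenoSurvExperiment(g, time = rexp(10) + 1,
#'                           status = rbinom(10, 1, 0.6))
#' snpMAF(gse)
#' @export
GenoSurvExperiment <- function(genotype, time = NULL, status = NULL,
                               covariates = NULL, snpInfo = NULL) {
  genotype <- as.matrix(genotype)
  storage.mode(genotype) <- "integer"
  if (is.null(colnames(genotype)))
    colnames(genotype) <- paste0("SNP", seq_len(ncol(genotype)))
  cd <- S4Vectors::DataFrame(row.names = seq_len(nrow(genotype)))
  if (!is.null(time)) {
    stopifnot(length(time) == nrow(genotype))
    cd$time <- as.numeric(time)
  }
  if (!is.null(status)) {
    stopifnot(length(status) == nrow(genotype))
    cd$status <- as.integer(status)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(genotype))
    for (nm in colnames(covariates)) cd[[nm]] <- covariates[[nm]]
  }
  rd <- if (is.null(snpInfo)) S4Vectors::DataFrame(row.names = colnames(genotype))
        else S4Vectors::DataFrame(snpInfo, row.names = colnames(genotype))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(genotype = t(genotype)),
    colData = cd, rowData = rd)
  methods::new("GenoSurvExperiment", se)
}

#' Fitted Cox proportional-hazards null model
#'
#' Holds the partial-likelihood MLE of a Cox model containing covariates
#' only (no genetic term), together with the Breslow estimate of the
#' baseline cumulative hazard.  With an empty covariate set the baseline
#' reduces to the Nelson-Aalen estimator.
#'
#' @slot coefficients named numeric vector of log hazard ratios (length 0
#'   for the covariate-free fit).
#' @slot vcov inverse observed information for the coefficients.
#' @slot baseline data.frame with columns `time`, `hazard` (jump) and
#'   `cumhaz`, one row per distinct event time; nondecreasing,
#'   right-continuous, 0 before the first event and carried flat beyond the
#'   last observed event time.
#' @slot loglik partial log-likelihood at convergence.
#' @slot iterations,converged Newton-Raphson bookkeeping.
#' @slot n,nevent subject and event counts.
#' @export
setClass("CoxNullFit",
  representation(coefficients = "numeric", vcov = "matrix",
                 baseline = "data.frame", loglik = "numeric",
                 iterations = "integer", converged = "logical",
                 n = "integer", nevent = "integer"))

#' Two-group log-rank decomposition
#'
#' @slot observed,expected per-event-time totals of observed and expected
#'   events in group 1.
#' @slot variance summed hypergeometric variance.
#' @slot statistic the standardized statistic
#'   \eqn{C = \sum(O_{1j}-E_{1j}) / \sqrt{\sum V_j}}.
#' @slot chisq the chi-square form \eqn{C^2} used by survival MDR.
#' @export
setClass("LogRankResult",
  representation(observed = "numeric", expected = "numeric",
                 variance = "numeric", statistic = "numeric",
                 chisq = "numeric"))

#' Result of a cross-validated exhaustive MDR scan
#'
#' @slot models `S4Vectors::DataFrame` with one row per evaluated model:
#'   `k`, comma-separated `snps`, `cvConsistency`, `meanTrainScore`,
#'   `testScore` (the model's per-fold out-of-sample statistics combined
#'   as sum/sqrt(folds)) and `nUsed`.
#' @slot best one row per interaction order `k`: the model chosen by
#'   cross-validation consistency, ties broken by mean training score,
#'   with the additional `cvTestScore` column holding the cross-validated
#'   prediction statistic (each fold winner's held-out statistic,
#'   combined as sum/sqrt(folds); squared for the survival-MDR scoring).
#' @slot overallBest index into `best` of the order whose chosen model has
#'   the largest cross-validated prediction statistic.
#' @slot method `"esmdr"` (t-statistic score) or `"survmdr"` (squared
#'   log-rank score).
#' @slot folds,seed cross-validation layout; the fold split is a seeded
#'   uniform random partition.
#' @slot snpIds SNP identifiers indexed by the model tuples.
#' @export
setClass("MDRResult",
  representation(models = "DataFrame", best = "DataFrame",
                 overallBest = "integer", method = "character",
                 folds = "integer", seed = "integer",
                 snpIds = "character", nSubjects = "integer"))

#' Purely epistatic two-locus penetrance model
#'
#' A 3x3 table \eqn{f_{ij} = P(\mathrm{high\ risk} \mid SNP1=i, SNP2=j)}
#' under Hardy-Weinberg genotype frequencies, constrained so that the
#' weighted marginal penetrance of each locus equals the prevalence (no
#' main effects) and the broad-sense heritability
#' \eqn{h^2 = \sum_{ij} p_i q_j (f_{ij}-K)^2 / (K(1-K))} hits its target.
#'
#' @slot f 3x3 penetrance table (rows = SNP1 dosage 0/1/2).
#' @slot maf shared minor allele frequency of the two functional loci.
#' @slot h2target,h2 requested and achieved heritability.
#' @slot prevalence marginal probability K of the high-risk state.
#' @export
setClass("PenetranceModel",
  representation(f = "matrix", maf = "numeric", h2target = "numeric",
                 h2 = "numeric", prevalence = "numeric"))

setValidity("PenetranceModel", function(object) {
  f <- object@f
  msg <- character()
  if (!all(dim(f) == c(3L, 3L))) msg <- c(msg, "f must be 3x3")
  if (any(f < 0 | f > 1)) msg <- c(msg, "penetrances must lie in [0, 1]")
  w <- hweWeights(object@maf)
  K <- object@prevalence
  marg <- c(as.vector(f %*% w), as.vector(t(w) %*% f))
  if (max(abs(marg - K)) > 1e-3)
    msg <- c(msg, "marginal penetrances must equal the prevalence (no main effects)")
  if (abs(object@h2 - object@h2target) > 0.05 * object@h2target)
    msg <- c(msg, "achieved heritability more than 5% from target")
  if (length(msg)) msg else TRUE
})
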