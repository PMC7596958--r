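#' Fit the covariate-only Cox null model
#'
#' Fits a Cox proportional-hazards model containing the adjustment
#' covariates only -- no genetic term -- by Newton-Raphson maximization of
#' the Breslow partial likelihood, and estimates the baseline cumulative
#' hazard with the Breslow estimator.  Its martingale residuals are the
#' continuous surrogate outcome that the ES-MDR scan classifies.  With no
#' covariates the fit degenerates to the Nelson-Aalen cumulative hazard.
#'
#' Ties in event times are handled with the Breslow approximation
#' throughout, so the baseline estimator, the partial likelihood and the
#' residuals are mutually consistent.  Convergence is declared when the
#' partial log-likelihood changes by less than `tol` (default 1e-9) between
#' iterations; step-halving guards against overshoot.
#'
#' @param x event/censoring times (nonnegative), or a
#'   [GenoSurvExperiment-class] whose `colData` supplies `time`, `status`
#'   and the covariates.
#' @param status event indicator, 1 = event, 0 = censored.
#' @param covariates optional numeric matrix/data.frame of per-subject
#'   covariates; `NULL` for the covariate-free fit.
#' @param tol,maxIter Newton-Raphson controls.
#' @return a [CoxNullFit-class].
#' @examples
#' fit <- fitCoxNull(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' fit@baseline$cumhaz  # Nelson-Aalen: 1/4, 1/4+1/3, ...
#' @rdname fitCoxNull
#' @export
setMethod("fitCoxNull", "numeric",
          function(x, status, covariates = NULL, tol = 1e-9, maxIter = 100L) {
  time <- as.numeric(x)
  status <- as.integer(status)
  n <- length(time)
  if (n < 2L) stop("need at least 2 subjects")
  if (length(status) != n) stop("time and status lengths differ")
  if (any(time < 0)) stop("times must be nonnegative")
  if (!all(status %in% c(0L, 1L))) stop("status must be 0/1")
  if (sum(status) < 1L) stop("no events")

  X <- NULL
  p <- 0L
  if (!is.null(covariates)) {
    X <- as.matrix(as.data.frame(covariates))
    storage.mode(X) <- "double"
    if (nrow(X) != n) stop("covariate matrix must have n rows")
    p <- ncol(X)
    if (p > 0L && qr(cbind(1, X))$rank < p + 1L)
      stop("covariate columns are constant or collinear")
    if (p == 0L) X <- NULL
  }

  ord <- order(time)
  ts <- time[ord]
  ev <- status[ord]
  Xs <- if (p) X[ord, , drop = FALSE] else NULL

  # risk set for time t = subjects with ts >= t; with ascending sort the
  # at-risk sum at the first index of a tie block is a reverse cumulative sum
  firstIdx <- which(!duplicated(ts))
  blockOf <- findInterval(seq_len(n), firstIdx)      # tie block per subject
  revcum <- function(v) rev(cumsum(rev(v)))

  eventBlocks <- sort(unique(blockOf[ev == 1L]))
  dBlock <- vapply(eventBlocks, function(b) sum(ev[blockOf == b]), 0)
  riskStart <- firstIdx[eventBlocks]

  beta <- rep(0, p)
  ll <- -Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    eta <- if (p) drop(Xs %*% beta) else rep(0, n)
    w <- exp(eta)
    S0 <- revcum(w)[riskStart]
    llNew <- sum(eta[ev == 1L]) - sum(dBlock * log(S0))
    if (p == 0L) { ll <- llNew; converged <- TRUE; break }

    if (iter > 0L && llNew < ll - 1e-12) {
      # overshoot: halve the last step
      beta <- (beta + betaPrev) / 2
      next
    }
    done <- iter > 0L && abs(llNew - ll) < tol
    ll <- llNew
    if (done) { converged <- TRUE; break }
    if (iter >= maxIter)
      stop(sprintf("Cox fit did not converge after %d iterations", iter))

    S1 <- matrix(0, length(riskStart), p)
    info <- matrix(0, p, p)
    for (a in seq_len(p)) S1[, a] <- revcum(w * Xs[, a])[riskStart]
    grad <- colSums(Xs[ev == 1L, , drop = FALSE]) -
      colSums(dBlock * (S1 / S0))
    for (a in seq_len(p)) for (b in a:p) {
      S2ab <- revcum(w * Xs[, a] * Xs[, b])[riskStart]
      v <- sum(dBlock * (S2ab / S0 - (S1[, a] / S0) * (S1[, b] / S0)))
      info[a, b] <- v
      info[b, a] <- v
    }
    betaPrev <- beta
    beta <- beta + solve(info, grad)
    iter <- iter + 1L
  }

  # Breslow baseline hazard increments at distinct event times
  eta <- if (p) drop(Xs %*% beta) else rep(0, n)
  S0 <- revcum(exp(eta))[riskStart]
  baseline <- data.frame(time = ts[riskStart], hazard = dBlock / S0)
  baseline$cumhaz <- cumsum(baseline$hazard)

  vc <- if (p) solve(info) else matrix(0, 0, 0)
  cf <- as.numeric(beta)
  names(cf) <- if (p) colnames(X) else character()
  methods::new("CoxNullFit", coefficients = cf, vcov = vc,
               baseline = baseline, loglik = ll, iterations = iter,
               converged = converged, n = n, nevent = sum(ev))
})

#' @rdname fitCoxNull
#' @param ... passed on to the numeric method.
#' @export
setMethod("fitCoxNull", "GenoSurvExperiment", function(x, ...) {
  fitCoxNull(eventTime(x), eventStatus(x), covariates = covariateMatrix(x),
             ...)
})

# Evaluate the baseline cumulative hazard at arbitrary times: a
# right-continuous step function, 0 before the first event, carried flat
# beyond the last jump.
baselineCumHaz <- function(fit, t) {
  bl <- fit@baseline
  idx <- findInterval(t, bl$time)
  c(0, bl$cumhaz)[idx + 1L]
}

#' Martingale residuals from a Cox null fit
#'
#' The martingale residual of subject \eqn{i} is
#' \deqn{M_i = \delta_i - \hat\Lambda_0(t_i)\, e^{\hat\beta' x_i},}
#' the difference between the observed and the model-expected number of
#' events.  Residuals are bounded above by 1 and, evaluated on the data the
#' model was fitted to, sum to zero.  Times beyond the last event are
#' handled by carrying the cumulative hazard forward.
#'
#' @param object a [CoxNullFit-class], or a [GenoSurvExperiment-class] (the
#'   null fit on its own `colData` covariates is then performed internally).
#' @param time,status,covariates the data to evaluate the residuals on;
#'   the covariate schema must match the fit.
#' @return numeric vector of residuals, one per subject.
#' @rdname martingaleResiduals
#' @export
setMethod("martingaleResiduals", "CoxNullFit",
          function(object, time, status, covariates = NULL) {
  p <- length(object@coefficients)
  eta <- if (p) {
    X <- as.matrix(as.data.frame(covariates))
    if (ncol(X) != p) stop("covariate schema does not match the fit")
    drop(X %*% object@coefficients)
  } else rep(0, length(time))
  as.integer(status) - baselineCumHaz(object, as.numeric(time)) * exp(eta)
})

#' @rdname martingaleResiduals
#' @param ... unused.
#' @export
setMethod("martingaleResiduals", "GenoSurvExperiment", function(object, ...) {
  fit <- fitCoxNull(object)
  martingaleResiduals(fit, eventTime(object), eventStatus(object),
                      covariates = covariateMatrix(object))
})

#' Two-group log-rank test
#'
#' Standard two-sample log-rank decomposition over the distinct event
#' times: observed events \eqn{O_{1j}} in group 1, expected events
#' \eqn{E_{1j} = d_j n_{1j}/n_j}, hypergeometric variance \eqn{V_j}, and the
#' standardized statistic \eqn{C = \sum(O_{1j}-E_{1j})/\sqrt{\sum V_j}}.
#' Its square is the chi-square form used as the survival-MDR score.  The
#' numerator \eqn{\sum(O_{1j}-E_{1j})} equals the sum of the
#' covariate-free martingale residuals over group 1 -- i.e. the log-rank
#' statistic with the variance set to 1 -- which is the identity ES-MDR
#' exploits.
#'
#' @param time,status survival outcome.
#' @param group binary (two-level) group membership of length n.
#' @return a [LogRankResult-class].
#' @export
logrankTest <- function(time, status, group) {
  time <- as.numeric(time)
  status <- as.integer(status)
  if (length(group) != length(time)) stop("group must have length n")
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L) stop("degenerate grouping")
  g1 <- g == 1L

  ord <- order(time)
  ts <- time[ord]; ev <- status[ord]; in1 <- g1[ord]
  firstIdx <- which(!duplicated(ts))
  blockOf <- findInterval(seq_len(length(ts)), firstIdx)
  revcum <- function(v) rev(cumsum(rev(v)))
  nAt <- revcum(rep(1, length(ts)))[firstIdx]
  n1At <- revcum(as.numeric(in1))[firstIdx]
  d <- tapply(ev, blockOf, sum)
  d1 <- tapply(ev * in1, blockOf, sum)
  keep <- d > 0
  d <- d[keep]; d1 <- d1[keep]
  nj <- nAt[keep]; n1j <- n1At[keep]
  O <- as.numeric(d1)
  E <- as.numeric(d * n1j / nj)
  V <- as.numeric(ifelse(nj > 1,
                         d * (n1j / nj) * (1 - n1j / nj) * (nj - d) / (nj - 1),
                         0))
  sv <- sum(V)
  stat <- if (sv > 0) sum(O - E) / sqrt(sv) else 0
  methods::new("LogRankResult", observed = O, expected = E, variance = sv,
               statistic = stat, chisq = stat^2)
}

#' Kaplan-Meier product-limit curves
#'
#' @param time,status survival outcome.
#' @param group optional group membership; one curve per level.
#' @return data.frame with columns `group`, `time`, `nRisk`, `nEvent`,
#'   `survival`, one row per distinct event time within each group.
#' @export
kmCurve <- function(time, status, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(time))
  if (length(group) != length(time)) stop("group must have length n")
  if (anyNA(group)) stop("group contains NA")
  lv <- if (is.factor(group)) levels(group) else unique(group)
  out <- lapply(lv, function(l) {
    sel <- group == l
    if (!any(sel)) stop("empty group")
    ts <- as.numeric(time[sel]); ev <- as.integer(status[sel])
    ord <- order(ts); ts <- ts[ord]; ev <- ev[ord]
    firstIdx <- which(!duplicated(ts))
    blockOf <- findInterval(seq_along(ts), firstIdx)
    nAt <- rev(cumsum(rev(rep(1, length(ts)))))[firstIdx]
    d <- as.numeric(tapply(ev, blockOf, sum))
    keep <- d > 0
    if (!any(keep))
      return(data.frame(group = rep(l, 0), time = numeric(0),
                        nRisk = numeric(0), nEvent = numeric(0),
                        survival = numeric(0)))
    data.frame(group = l, time = ts[firstIdx][keep], nRisk = nAt[keep],
               nEvent = d[keep],
               survival = cumprod(1 - d[keep] / nAt[keep]))
  })
  do.call(rbind, out)
}

# Product-limit survival evaluated at a single time point.
kmAt <- function(time, status, at) {
  if (!length(time)) return(1)
  cur <- kmCurve(time, status)
  idx <- findInterval(at, cur$time)
  if (idx == 0L) 1 else cur$survival[idx]
}
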