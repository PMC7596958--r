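# Shared fixtures, all generated in code.

# Censored survival data with one binary and one continuous covariate.
makeSurvData <- function(n, seed, betas = c(0.5, -0.3), censorMax = 3) {
  withr::with_seed(seed, {
    x1 <- stats::rbinom(n, 1, 0.4)
    x2 <- stats::rnorm(n)
    evt <- stats::rexp(n, exp(betas[1] * x1 + betas[2] * x2))
    cens <- stats::runif(n, 0, censorMax)
    list(time = pmin(evt, cens), status = as.integer(evt <= cens),
         covariates = data.frame(x1 = x1, x2 = x2))
  })
}

# Small genotype matrix with independent SNPs.
makeGeno <- function(n, m, seed, maf = NULL) {
  withr::with_seed(seed, {
    if (is.null(maf)) maf <- stats::runif(m, 0.1, 0.5)
    g <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
    colnames(g) <- paste0("SNP", seq_len(m))
    g
  })
}

# Textbook two-sample pooled t, the oracle for tScore.
oracleT <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
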