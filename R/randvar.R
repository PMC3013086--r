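#' Random-variance arm configuration
#'
#' @param p_threshold Gene-wise significance level; default 0.001.
#' @param prior_source \code{"fitted"} (marginal-ML fit of the variance
#'   prior), \code{"none"} (no shrinkage: ordinary pooled t-test), or a
#'   numeric \code{c(a =, b =)} pair for a fixed prior.
#' @return A list of class \code{RVMConfig}.
#' @export
rvmConfig <- function(p_threshold = 0.001, prior_source = "fitted") {
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must be in (0, 1)")
  if (is.character(prior_source))
    prior_source <- match.arg(prior_source, c("fitted", "none"))
  else if (!(is.numeric(prior_source) && length(prior_source) == 2L &&
             all(prior_source > 0)))
    stop("prior_source must be 'fitted', 'none', or c(a, b) > 0")
  structure(list(p_threshold = p_threshold,
                 prior_source = prior_source),
            class = "RVMConfig")
}

#' Quantile-normalize a matrix of log2 intensities
#'
#' Makes every column's empirical distribution identical: each column's
#' sorted values are replaced by the row-wise mean of the sorted
#' columns, with tied ranks receiving the average of the tied values.
#'
#' @param m Numeric matrix (genes in rows, arrays in columns).
#' @return The quantile-normalized matrix.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
#' @export
quantileNormalize <- function(m) {
  out <- limma::normalizeQuantiles(as.matrix(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

# Negative marginal log-likelihood of gene variances under the
# random-variance model: s2 * a * b ~ F(d, 2a), i.e. precisions
# tau = 1/sigma^2 ~ Gamma(shape a, rate r = 1/b) and
# s2 | tau ~ Gamma(d/2, rate d * tau / 2).
rvmNegLogLik <- function(log_ab, s2, d) {
  a <- exp(log_ab[1L]); r <- exp(log_ab[2L])  # r = 1/b
  ll <- (d / 2) * log(d / 2) + (d / 2 - 1) * log(s2) + a * log(r) +
    lgamma(d / 2 + a) - lgamma(d / 2) - lgamma(a) -
    (d / 2 + a) * log(d * s2 / 2 + r)
  -sum(ll)
}

#' Fit the inverse-gamma variance prior by marginal maximum likelihood
#'
#' Under the random-variance model gene precisions follow
#' \code{Gamma(a, scale = b)} and each observed residual variance is a
#' scaled chi-square with \code{df} degrees of freedom, so that
#' \code{s2 * a * b ~ F(df, 2a)}. The marginal likelihood of the
#' observed variances is maximized numerically over \code{(a, b)},
#' initialized by method of moments. In the degenerate limit where all
#' variances are (nearly) equal the prior concentrates: \code{a} is
#' capped at 1e6 and the shrinkage target \code{1/(a b)} equals the
#' common variance, so the regularized variance returns that value.
#'
#' @param variances Numeric vector of per-gene residual variances
#'   (>= 100 genes).
#' @param df Residual degrees of freedom of each variance (scalar).
#' @return A \linkS4class{VariancePrior}.
#' @examples
#' set.seed(1)
#' tau <- rgamma(2000, shape = 2, scale = 1.5)
#' s2 <- (1 / tau) * rchisq(2000, 4) / 4
#' fitVariancePrior(s2, 4)
#' @export
fitVariancePrior <- function(variances, df) {
  s2 <- variances[is.finite(variances) & variances > 0]
  if (length(s2) < 100L) stop("need >= 100 positive gene variances")
  if (df < 1) stop("df must be >= 1")
  m <- mean(s2)
  if (stats::sd(s2) / m < 1e-8) {  # equal-variance limit
    a <- 1e6
    return(methods::new("VariancePrior", a = a, b = 1 / (a * m),
                        logLik = NA_real_,
                        nGenes = length(s2)))
  }
  # method-of-moments start: E[s2] = 1 / (b (a - 1)) for a > 1
  a0 <- 2
  r0 <- m * (a0 - 1)  # rate = 1/b
  fit <- stats::optim(c(log(a0), log(r0)), rvmNegLogLik, s2 = s2, d = df,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0)
    stop("variance-prior fit did not converge (code ",
         fit$convergence, ")")
  a <- min(exp(fit$par[1L]), 1e6)
  r <- exp(fit$par[2L])
  methods::new("VariancePrior", a = a, b = 1 / r, logLik = -fit$value,
               nGenes = length(s2))
}

#' Random-variance (shrinkage) t-test
#'
#' A two-sample pooled t-test whose per-gene variance is regularized
#' toward the prior: \code{reg = (d * s2 + 2a * target) / (d + 2a)} with
#' \code{d = n1 + n2 - 2}, shrinkage target \code{1/(a b)} and
#' degrees of freedom \code{d + 2a}. With \code{prior = NULL} (or
#' \code{a -> 0}) the statistic is exactly the ordinary pooled
#' t-statistic.
#'
#' @param values Gene-by-array numeric matrix (log2 scale).
#' @param classes Character vector of two class labels.
#' @param prior A \linkS4class{VariancePrior}, or \code{NULL} for no
#'   shrinkage.
#' @return data.frame with per-gene \code{statistic}, \code{p_value},
#'   \code{mean_class1}, \code{mean_class2}, \code{s2} (pooled sample
#'   variance) and \code{s2_reg} (regularized variance).
#' @export
rvmTTest <- function(values, classes, prior = NULL) {
  values <- rbind(values)
  cls <- sort(unique(classes))
  stopifnot(length(cls) == 2L)
  X1 <- values[, classes == cls[1L], drop = FALSE]
  X2 <- values[, classes == cls[2L], drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 arrays per class")
  d <- n1 + n2 - 2L
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  ss <- rowSums((X1 - m1)^2) + rowSums((X2 - m2)^2)
  s2 <- ss / d
  if (is.null(prior)) {
    a <- 0; target <- 0
  } else {
    stopifnot(methods::is(prior, "VariancePrior"))
    a <- prior@a; target <- 1 / (prior@a * prior@b)
  }
  s2_reg <- (d * s2 + 2 * a * target) / (d + 2 * a)
  if (any(s2_reg == 0))
    stop("undefined statistic: zero variance and no prior mass")
  tt <- (m2 - m1) / sqrt(s2_reg * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tt), d + 2 * a)
  data.frame(statistic = tt, p_value = p, mean_class1 = m1,
             mean_class2 = m2, s2 = s2, s2_reg = s2_reg,
             row.names = rownames(values))
}

#' Random-variance class comparison arm
#'
#' The second differential-expression arm: raw intensities are floored
#' at 1 and log2-transformed, quantile normalization equalizes the
#' array distributions, the variance prior is fitted across all genes,
#' and each gene is tested by the random-variance t-test. Genes are
#' significant at \code{p_threshold} (default 0.001); no fold filter is
#' applied in this arm.
#'
#' @param be A \linkS4class{BeaconExperiment} (only the \code{"raw"}
#'   assay is used; this arm normalizes independently of the noise-SD
#'   pipeline).
#' @param config An [rvmConfig()].
#' @return data.frame with \code{gene}, \code{mean_class1},
#'   \code{mean_class2} (log2 units), \code{fold} (linear, from the
#'   log2 difference), \code{statistic}, \code{p_value},
#'   \code{direction}, \code{passed_filters},
#'   \code{arm = "random_variance"}. The fitted prior is attached as
#'   attribute \code{"prior"}.
#' @export
classComparison <- function(be, config = rvmConfig()) {
  stopifnot(methods::is(be, "BeaconExperiment"))
  lg <- log2(pmax(rawValues(be), 1))
  lg <- quantileNormalize(lg)
  classes <- classLabels(be)
  cls <- sort(unique(classes))
  n1 <- sum(classes == cls[1L]); n2 <- sum(classes == cls[2L])
  prior <- NULL
  if (is.numeric(config$prior_source)) {
    prior <- methods::new("VariancePrior", a = config$prior_source[1L],
                          b = config$prior_source[2L],
                          logLik = NA_real_, nGenes = 0L)
  } else if (config$prior_source == "fitted") {
    m1 <- rowMeans(lg[, classes == cls[1L], drop = FALSE])
    m2 <- rowMeans(lg[, classes == cls[2L], drop = FALSE])
    ss <- rowSums((lg[, classes == cls[1L], drop = FALSE] - m1)^2) +
      rowSums((lg[, classes == cls[2L], drop = FALSE] - m2)^2)
    prior <- fitVariancePrior(ss / (n1 + n2 - 2L), n1 + n2 - 2L)
  }
  tst <- rvmTTest(lg, classes, prior)
  ld <- tst$mean_class2 - tst$mean_class1
  res <- data.frame(gene = rownames(lg),
                    mean_class1 = tst$mean_class1,
                    mean_class2 = tst$mean_class2,
                    fold = 2^abs(ld),
                    statistic = tst$statistic, p_value = tst$p_value,
                    direction = ifelse(ld >= 0, "up", "down"),
                    passed_filters = tst$p_value < config$p_threshold,
                    arm = "random_variance", row.names = NULL)
  attr(res, "alpha") <- config$p_threshold
  attr(res, "prior") <- prior
  res
}
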