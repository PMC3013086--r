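#' Associative-analysis configuration
#'
#' @param f_test_alpha Significance level of the F-test admitting genes
#'   into the low-variability reference group; default 0.05.
#' @param assoc_alpha Per-gene significance level; \code{NULL} (default)
#'   means Bonferroni \code{0.05 / n_tested}, controlling family-wise
#'   error over the expressed genes.
#' @param fold_threshold Minimum linear fold change; default 1.5.
#' @param expression_sd_threshold Minimum expression of the larger class
#'   mean, in noise-SD units; default 20.
#' @param fold_scale \code{"linear"} (default): fold changes are ratios
#'   of class means in linear noise-SD units (floored at 1);
#'   \code{"log"}: ratios of 10^log10-values, equivalent here but kept
#'   as an explicit switch.
#' @return A list of class \code{AssociativeConfig}.
#' @export
associativeConfig <- function(f_test_alpha = 0.05, assoc_alpha = NULL,
                              fold_threshold = 1.5,
                              expression_sd_threshold = 20,
                              fold_scale = c("linear", "log")) {
  if (f_test_alpha <= 0 || f_test_alpha >= 1)
    stop("f_test_alpha must be in (0, 1)")
  if (!is.null(assoc_alpha) && (assoc_alpha <= 0 || assoc_alpha >= 1))
    stop("assoc_alpha must be in (0, 1)")
  if (fold_threshold <= 0 || expression_sd_threshold <= 0)
    stop("thresholds must be > 0")
  structure(list(f_test_alpha = f_test_alpha, assoc_alpha = assoc_alpha,
                 fold_threshold = fold_threshold,
                 expression_sd_threshold = expression_sd_threshold,
                 fold_scale = match.arg(fold_scale)),
            class = "AssociativeConfig")
}

# Truncation-bias correction for the pooled variance of the lowest k of
# n null variances: E[X | X <= q_p] for X ~ chi2_d / d equals
# P(chi2_{d+2} <= qchisq(p, d)) / p, so dividing the truncated mean by
# this factor makes it unbiased for the common variance.
truncationFactor <- function(p, d) {
  pchisq(stats::qchisq(p, d), d + 2) / p
}

#' Select the low-variability reference gene group
#'
#' From the genes expressed in all arrays, ranked by their total
#' variability about their own grand mean over the combined dataset,
#' the reference group is grown from the low-variability end: each gene
#' is admitted when the F-statistic of its total variance against the
#' (truncation-bias-corrected) pooled within-class variance of the
#' current group is not significant at \code{f_test_alpha}. Ranking on
#' total variability is what keeps differentially expressed genes out:
#' their between-class component inflates the grand-mean variance even
#' though their within-class scatter is ordinary. The admitted genes'
#' within-class residuals, pooled and rescaled for the low-variance
#' selection bias, represent the technical variability of the assay and
#' define the null of the associative t-test.
#'
#' @param be A normalized \linkS4class{BeaconExperiment} with at least 4
#'   arrays (2 per class).
#' @param config An [associativeConfig()].
#' @return A \linkS4class{ReferenceGroup}.
#' @export
selectReferenceGroup <- function(be, config = associativeConfig()) {
  z <- normalizedValues(be)
  mask <- expressedMask(be)
  classes <- classLabels(be)
  tab <- table(classes)
  if (length(tab) != 2L || any(tab < 2L))
    stop("need two classes with >= 2 arrays each")
  n_arrays <- ncol(z)
  d_sel <- n_arrays - 1L  # df of the grand-mean (total) variance
  d_res <- n_arrays - 2L  # df of the within-class residuals
  cand <- which(rowSums(!mask) == 0L)
  if (length(cand) < 30L)
    stop("reference group too small: fewer than 30 genes expressed in ",
         "all arrays")
  zc <- z[cand, , drop = FALSE]
  v_tot <- rowSums((zc - rowMeans(zc))^2) / d_sel
  res <- zc
  for (cl in names(tab)) {
    jj <- classes == cl
    res[, jj] <- zc[, jj, drop = FALSE] -
      rowMeans(zc[, jj, drop = FALSE])
  }
  ss_w <- rowSums(res^2)
  ord <- order(v_tot, rownames(zc))  # tie-break by id for determinism
  n <- length(ord)

  admit <- logical(n)
  k <- 0L; ss_adm <- 0
  for (i in ord) {
    ok <- if (k < 30L) TRUE else {
      sigma2 <- (ss_adm / (k * d_res)) /
        truncationFactor(k / n, d_sel)
      p <- pf(v_tot[i] / sigma2, d_sel, k * d_res,
              lower.tail = FALSE)
      p >= config$f_test_alpha
    }
    if (ok) {
      admit[i] <- TRUE
      k <- k + 1L
      ss_adm <- ss_adm + ss_w[i]
    }
  }

  # The admitted genes are the lowest-variability fraction, so their
  # raw pooled residual variance under-estimates the technical
  # variance. The truncation quantile is estimated self-consistently
  # from the largest admitted total variance (robust to high-variance
  # contamination of the candidate pool), and the pool is rescaled by
  # the corresponding chi-square truncation factor.
  pooled <- as.numeric(t(res[admit, , drop = FALSE]))
  raw_var <- sum(pooled^2) / (k * d_res)
  v_thr <- max(v_tot[admit])
  sigma2 <- raw_var
  for (it in 1:5) {
    p_hat <- min(max(pchisq(d_sel * v_thr / sigma2, d_sel), 0.5),
                 1 - 1e-9)
    sigma2 <- raw_var / truncationFactor(p_hat, d_sel)
  }
  pooled <- pooled * sqrt(sigma2 / raw_var)
  pooled_sd <- sqrt(sum(pooled^2) / (k * d_res))
  methods::new("ReferenceGroup",
               geneIds = rownames(zc)[admit],
               pooledResiduals = pooled,
               pooledSd = pooled_sd,
               df = k * d_res)
}

#' Associative t-test of genes against the reference group
#'
#' For each gene and each class, the gene's replicate deviations from
#' the \emph{other} class's mean are compared by a standard two-sample
#' (pooled-variance Student) t-test against the pooled reference
#' residuals. Under the null the gene's values in that condition
#' scatter with technical variability around an unchanged mean, i.e.
#' the gene is "associated with" the reference group. The standard
#' error of the mean deviation includes the sampling noise of the other
#' class's mean (\code{1/n_other}); the pooled variance combines the
#' gene's deviation variance (whose expectation is the per-observation
#' technical variance, since the shared other-mean term cancels in a
#' sample variance) with the reference pool, giving
#' \code{n_test + N - 2} degrees of freedom. The reported per-gene
#' p-value is the minimum over the two directed comparisons (two-sided
#' p).
#'
#' @param values Gene-by-array numeric matrix in noise-SD units.
#' @param classes Character vector of class labels (two classes).
#' @param reference A \linkS4class{ReferenceGroup}.
#' @return data.frame with per-gene \code{statistic} (t of the winning
#'   comparison) and \code{p_value}.
#' @export
associativeTTest <- function(values, classes, reference) {
  stopifnot(methods::is(reference, "ReferenceGroup"))
  values <- rbind(values)  # promote a vector to a 1-row matrix
  r <- reference@pooledResiduals
  if (length(r) < 100L)
    stop("reference pool too small: need >= 100 pooled residuals")
  N <- length(r)
  r_mean <- mean(r)  # identically 0 by within-class centering
  r_var <- reference@pooledSd^2  # df-correct technical variance
  df_r <- reference@df
  cls <- sort(unique(classes))
  one <- function(test_class) {
    other <- setdiff(cls, test_class)
    Xt <- values[, classes == test_class, drop = FALSE]
    Xo <- values[, classes == other, drop = FALSE]
    m_other <- rowMeans(Xo)
    D <- Xt - m_other
    nc <- ncol(Xt)
    no <- ncol(Xo)
    m_d <- rowMeans(D)
    v_d <- rowVars(D)  # expectation = technical variance (shared
                       # other-mean term cancels in the sample variance)
    if (any(v_d == 0 & r_var == 0, na.rm = TRUE))
      stop("undefined statistic: zero variance in gene and reference")
    df <- (nc - 1L) + df_r
    s2_pool <- ((nc - 1) * v_d + df_r * r_var) / df
    tt <- (m_d - r_mean) /
      sqrt(s2_pool * (1 / nc + 1 / no + 1 / N))
    p <- 2 * pt(-abs(tt), df)
    list(t = tt, p = p)
  }
  a <- one(cls[1L]); b <- one(cls[2L])
  use_b <- b$p <= a$p
  data.frame(statistic = ifelse(use_b, b$t, a$t),
             p_value = pmin(a$p, b$p),
             row.names = rownames(values))
}

# Linear fold change between class means floored at `floor`.
foldChange <- function(m1, m2, floor = 1) {
  r <- pmax(m2, floor) / pmax(m1, floor)
  pmax(r, 1 / r)
}

#' Apply the significance, fold-change and expression filters
#'
#' Keeps genes significant at \code{assoc_alpha} with a linear fold
#' change of at least \code{fold_threshold} (default 1.5) and the larger
#' class mean at least \code{expression_sd_threshold} noise-SD (default
#' 20) above background. Direction is the sign of the class-2 vs class-1
#' mean difference.
#'
#' @param results A DE result data.frame with columns
#'   \code{mean_class1}, \code{mean_class2}, \code{fold},
#'   \code{p_value}.
#' @param config An [associativeConfig()].
#' @param alpha Per-gene significance level actually used (resolves the
#'   Bonferroni default); computed from \code{nrow(results)} when
#'   \code{config$assoc_alpha} is \code{NULL}.
#' @return The table with \code{passed_filters} and \code{direction}
#'   columns set.
#' @export
applyDeFilters <- function(results, config = associativeConfig(),
                           alpha = NULL) {
  if (is.null(alpha))
    alpha <- if (!is.null(config$assoc_alpha)) config$assoc_alpha
             else 0.05 / nrow(results)
  results$direction <- ifelse(results$mean_class2 >= results$mean_class1,
                              "up", "down")
  results$passed_filters <- results$p_value < alpha &
    results$fold >= config$fold_threshold &
    pmax(results$mean_class1, results$mean_class2) >=
      config$expression_sd_threshold
  attr(results, "alpha") <- alpha
  results
}

#' Associative differential-expression arm
#'
#' Runs the full associative analysis on a normalized study: select the
#' reference group, test every gene expressed in all arrays against it,
#' and apply the fold-change and expression filters.
#'
#' @param be A normalized \linkS4class{BeaconExperiment}.
#' @param config An [associativeConfig()].
#' @return data.frame (one row per tested gene): \code{gene},
#'   \code{mean_class1}, \code{mean_class2} (noise-SD units),
#'   \code{fold}, \code{statistic}, \code{p_value}, \code{direction},
#'   \code{passed_filters}, \code{arm = "associative"}. The resolved
#'   per-gene alpha is attached as attribute \code{"alpha"}, the
#'   reference group as attribute \code{"reference"}.
#' @examples
#' be <- simulateExpression(expressionSimConfig(
#'   n_probes = 3000, n_de = 20, fold_changes = 4,
#'   signal_log_mean = log(2000), signal_log_sd = 0.4, seed = 11))
#' be <- normalizeExperiment(be)
#' de <- associativeDE(be)
#' sum(de$passed_filters)
#' @export
associativeDE <- function(be, config = associativeConfig()) {
  z <- normalizedValues(be)
  mask <- expressedMask(be)
  classes <- classLabels(be)
  reference <- selectReferenceGroup(be, config)
  tested <- which(rowSums(!mask) == 0L)
  zt <- z[tested, , drop = FALSE]
  tst <- associativeTTest(zt, classes, reference)
  cls <- sort(unique(classes))
  m1 <- rowMeans(zt[, classes == cls[1L], drop = FALSE])
  m2 <- rowMeans(zt[, classes == cls[2L], drop = FALSE])
  res <- data.frame(gene = rownames(zt),
                    mean_class1 = m1, mean_class2 = m2,
                    fold = foldChange(m1, m2),
                    statistic = tst$statistic, p_value = tst$p_value,
                    arm = "associative", row.names = NULL)
  res <- applyDeFilters(res, config)
  attr(res, "reference") <- reference
  res
}
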