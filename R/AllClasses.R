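#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median IQR pf pt pchisq qf phyper rnorm rlnorm rbinom
#'   runif var sd optim p.adjust quantile coef setNames
#' @importFrom utils read.delim write.table
NULL

#' Per-array Gaussian noise model
#'
#' Holds the mean and standard deviation of the Gaussian fitted to the
#' low-expression (noise) mode of one array's raw-intensity histogram.
#' The fitted mean is the normalization origin and the fitted SD is the
#' unit in which all downstream "SD above noise" thresholds are stated.
#'
#' @slot mean Numeric scalar, location of the noise mode (intensity units).
#' @slot sd Numeric scalar, noise standard deviation (intensity units),
#'   strictly positive.
#'
#' @seealso [fitNoiseDistribution()]
#' @export
setClass("NoiseModel", slots = c(mean = "numeric", sd = "numeric"))

setValidity("NoiseModel", function(object) {
  if (length(object@mean) != 1L || length(object@sd) != 1L)
    return("mean and sd must be scalars")
  if (!is.finite(object@mean) || !is.finite(object@sd))
    return("mean and sd must be finite")
  if (object@sd <= 0) return("sd must be > 0")
  TRUE
})

#' Two-class expression study container
#'
#' A \linkS4class{SummarizedExperiment} carrying a probe-by-array intensity
#' matrix in the \code{"raw"} assay and a two-level \code{class_label}
#' column in \code{colData}. Normalization adds \code{"normalized"}
#' (noise-SD units), \code{"log10"} and \code{"expressed"} assays plus
#' per-array noise-model and alignment columns to \code{colData}.
#' Simulated studies additionally record planted truth in
#' \code{metadata()}: \code{truth_expressed}, \code{truth_de} (named
#' vector of planted linear fold changes) and the generating config.
#'
#' @seealso [BeaconExperiment()], [simulateExpression()],
#'   [normalizeExperiment()]
#' @export
setClass("BeaconExperiment", contains = "SummarizedExperiment")

setValidity("BeaconExperiment", function(object) {
  if (!("raw" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'raw' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!("class_label" %in% colnames(cd)))
    return("colData column 'class_label' is required")
  if (any(SummarizedExperiment::assay(object, "raw") < 0, na.rm = TRUE))
    return("raw intensities must be non-negative")
  TRUE
})

#' Low-variability reference gene group
#'
#' The F-test-selected group of expressed genes whose expression
#' variability is indistinguishable from technical variability; their
#' pooled residuals define the null of the associative t-test.
#'
#' @slot geneIds Character vector of member gene/probe ids.
#' @slot pooledResiduals Numeric vector of per-gene deviations from
#'   per-class means, concatenated over member genes (noise-SD units).
#' @slot pooledSd Numeric scalar, SD of the pooled residuals computed
#'   on their true degrees of freedom (each gene contributes
#'   \code{n_arrays - 2} df, not \code{n_arrays}, because the residuals
#'   are centered within each class).
#' @slot df Integer scalar, residual degrees of freedom of the pool.
#'
#' @seealso [selectReferenceGroup()], [associativeTTest()]
#' @export
setClass("ReferenceGroup",
         slots = c(geneIds = "character", pooledResiduals = "numeric",
                   pooledSd = "numeric", df = "integer"))

setValidity("ReferenceGroup", function(object) {
  if (length(object@pooledSd) != 1L || !is.finite(object@pooledSd) ||
      object@pooledSd <= 0)
    return("pooledSd must be a positive scalar")
  TRUE
})

#' Inverse-gamma variance prior for the random-variance t-test
#'
#' Parameters of the gamma prior on gene-level precisions
#' (1/sigma^2 ~ Gamma(shape = a, scale = b)) fitted across all genes by
#' marginal maximum likelihood. The shrinkage target of the regularized
#' variance is 1/(a*b) and the degrees-of-freedom gain is 2a.
#'
#' @slot a Numeric scalar shape, > 0 (may be very large in the
#'   equal-variance limit).
#' @slot b Numeric scalar scale, > 0.
#' @slot logLik Numeric scalar, maximized marginal log-likelihood.
#' @slot nGenes Integer, number of gene variances used in the fit.
#'
#' @seealso [fitVariancePrior()], [rvmTTest()]
#' @export
setClass("VariancePrior",
         slots = c(a = "numeric", b = "numeric", logLik = "numeric",
                   nGenes = "integer"))

setValidity("VariancePrior", function(object) {
  if (object@a <= 0 || object@b <= 0) return("a and b must be > 0")
  TRUE
})

#' Weighted term co-occurrence network
#'
#' Symmetric non-negative object-by-object weight matrix built from
#' same-sentence / same-abstract co-mentions, plus per-object document
#' frequency and the object table (id, kind) of the thesaurus.
#'
#' @slot weights Symmetric numeric matrix, objects in rows/columns.
#' @slot docFreq Named numeric vector: abstracts mentioning each object.
#' @slot objects data.frame with columns \code{object_id}, \code{kind}.
#'
#' @seealso [buildNetwork()], [sharedTermEnrichment()]
#' @export
setClass("CooccurrenceNetwork",
         slots = c(weights = "matrix", docFreq = "numeric",
                   objects = "data.frame"))

setValidity("CooccurrenceNetwork", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12)))
    return("weights must be symmetric")
  if (any(w < 0)) return("weights must be non-negative")
  if (length(object@docFreq) != nrow(w))
    return("docFreq length must match weights dimension")
  TRUE
})

#' Beacon gene lists from the two DE arms
#'
#' Directional gene lists from the associative and random-variance arms
#' and their per-direction intersections (the "beacon" genes), plus an
#' overlap report (sizes, intersection sizes, subset flags) and any genes
#' excluded because the two arms disagreed on direction.
#'
#' @slot upAssoc,downAssoc,upRvm,downRvm,upBeacon,downBeacon Character
#'   vectors of gene ids.
#' @slot report data.frame overlap diagnostics per direction.
#' @slot conflicts Character vector of direction-conflicted genes.
#'
#' @seealso [integrateLists()]
#' @export
setClass("BeaconLists",
         slots = c(upAssoc = "character", downAssoc = "character",
                   upRvm = "character", downRvm = "character",
                   upBeacon = "character", downBeacon = "character",
                   report = "data.frame", conflicts = "character"))

setValidity("BeaconLists", function(object) {
  if (!setequal(object@upBeacon, intersect(object@upAssoc, object@upRvm)) &&
      length(object@conflicts) == 0L)
    return("upBeacon must be the intersection of the up lists")
  if (length(intersect(object@upBeacon, object@downBeacon)) > 0L)
    return("beacon sets must be disjoint")
  TRUE
})
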