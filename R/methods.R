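#' Construct a two-class expression study
#'
#' Wraps a probe-by-array raw intensity matrix and its class labels into a
#' \linkS4class{BeaconExperiment}.
#'
#' @param raw Non-negative numeric matrix, probes in rows, arrays in
#'   columns. Dimnames are used as probe/array ids; defaults are
#'   generated when absent.
#' @param class_labels Character/factor vector, one label per array;
#'   exactly two distinct labels for the DE stages.
#' @param metadata Optional list stored in \code{metadata()}.
#' @return A \linkS4class{BeaconExperiment}.
#' @examples
#' m <- matrix(rexp(20, 1 / 50), nrow = 5,
#'             dimnames = list(paste0("p", 1:5), paste0("a", 1:4)))
#' be <- BeaconExperiment(m, c("class1", "class1", "class2", "class2"))
#' classLabels(be)
#' @export
BeaconExperiment <- function(raw, class_labels, metadata = list()) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("raw must be a numeric matrix")
  if (anyNA(raw)) stop("raw must not contain missing values")
  if (is.null(rownames(raw)))
    rownames(raw) <- sprintf("probe_%05d", seq_len(nrow(raw)))
  if (is.null(colnames(raw)))
    colnames(raw) <- sprintf("array_%02d", seq_len(ncol(raw)))
  class_labels <- as.character(class_labels)
  if (length(class_labels) != ncol(raw))
    stop("need one class label per array")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw),
    colData = S4Vectors::DataFrame(class_label = class_labels,
                                   row.names = colnames(raw)),
    metadata = metadata)
  methods::new("BeaconExperiment", se)
}

#' @describeIn BeaconExperiment class labels accessor
#' @param x A \code{BeaconExperiment}.
#' @export
setMethod("classLabels", "BeaconExperiment", function(x)
  as.character(SummarizedExperiment::colData(x)$class_label))

#' @export
setMethod("rawValues", "BeaconExperiment", function(x)
  SummarizedExperiment::assay(x, "raw"))

.assayOrStop <- function(x, name) {
  if (!(name %in% SummarizedExperiment::assayNames(x)))
    stop("assay '", name, "' not present; run normalizeExperiment() first")
  SummarizedExperiment::assay(x, name)
}

#' @export
setMethod("normalizedValues", "BeaconExperiment", function(x)
  .assayOrStop(x, "normalized"))

#' @export
setMethod("logValues", "BeaconExperiment", function(x)
  .assayOrStop(x, "log10"))

#' @export
setMethod("expressedMask", "BeaconExperiment", function(x)
  .assayOrStop(x, "expressed") > 0)

#' @export
setMethod("noiseModels", "BeaconExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!("noise_mean" %in% colnames(cd)))
    stop("no noise models; run normalizeExperiment() first")
  data.frame(array_id = rownames(cd), noise_mean = cd$noise_mean,
             noise_sd = cd$noise_sd, row.names = NULL)
})

#' @export
setMethod("alignmentParams", "BeaconExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!("align_slope" %in% colnames(cd)))
    stop("no alignment parameters; run normalizeExperiment() first")
  data.frame(array_id = rownames(cd), slope = cd$align_slope,
             intercept = cd$align_intercept, row.names = NULL)
})

#' @export
setMethod("truthExpressed", "BeaconExperiment", function(x) {
  te <- S4Vectors::metadata(x)$truth_expressed
  if (is.null(te)) stop("no planted truth: not a simulated study")
  te
})

#' @export
setMethod("truthDe", "BeaconExperiment", function(x) {
  td <- S4Vectors::metadata(x)$truth_de
  if (is.null(td)) stop("no planted truth: not a simulated study")
  td
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: mean = %.4g, sd = %.4g (intensity units)\n",
              object@mean, object@sd))
})

setMethod("show", "BeaconExperiment", function(object) {
  cl <- table(classLabels(object))
  cat(sprintf("BeaconExperiment: %d probes x %d arrays (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s: %d", names(cl), cl), collapse = ", ")))
  cat("assays:", paste(SummarizedExperiment::assayNames(object),
                       collapse = ", "), "\n")
  if (!is.null(S4Vectors::metadata(object)$truth_de))
    cat(sprintf("simulated study: %d expressed, %d DE probes planted\n",
                length(S4Vectors::metadata(object)$truth_expressed),
                length(S4Vectors::metadata(object)$truth_de)))
})

setMethod("show", "ReferenceGroup", function(object) {
  cat(sprintf(
    "ReferenceGroup: %d genes, %d pooled residuals (%d df), pooled SD = %.4g\n",
    length(object@geneIds), length(object@pooledResiduals),
    object@df, object@pooledSd))
})

setMethod("show", "VariancePrior", function(object) {
  cat(sprintf(
    "VariancePrior: a = %.4g, b = %.4g (target variance %.4g, df gain %.3g)\n",
    object@a, object@b, 1 / (object@a * object@b), 2 * object@a))
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  nz <- sum(object@weights[upper.tri(object@weights)] > 0)
  cat(sprintf("CooccurrenceNetwork: %d objects, %d weighted edges\n",
              nrow(object@weights), nz))
})

setMethod("show", "BeaconLists", function(object) {
  cat(sprintf(
    "BeaconLists: up %d & %d -> %d beacons; down %d & %d -> %d beacons\n",
    length(object@upAssoc), length(object@upRvm), length(object@upBeacon),
    length(object@downAssoc), length(object@downRvm),
    length(object@downBeacon)))
  if (length(object@conflicts))
    cat("direction conflicts excluded:",
        paste(object@conflicts, collapse = ", "), "\n")
})

#' Accessors for ReferenceGroup
#' @param x A \linkS4class{ReferenceGroup}.
#' @return Member gene ids / pooled residual vector / pooled SD.
#' @export
referenceGeneIds <- function(x) x@geneIds

#' @rdname referenceGeneIds
#' @export
pooledResiduals <- function(x) x@pooledResiduals

#' @rdname referenceGeneIds
#' @export
pooledSd <- function(x) x@pooledSd

#' Accessors for BeaconLists
#' @param x A \linkS4class{BeaconLists}.
#' @param direction "up" or "down".
#' @return Character vector of gene ids (beacons), or the overlap report
#'   data.frame.
#' @export
beaconGenes <- function(x, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (direction == "up") x@upBeacon else x@downBeacon
}

#' @rdname beaconGenes
#' @export
overlapReport <- function(x) x@report

#' Network accessors
#' @param x A \linkS4class{CooccurrenceNetwork}.
#' @return The symmetric weight matrix / named document-frequency vector.
#' @export
networkWeights <- function(x) x@weights

#' @rdname networkWeights
#' @export
documentFrequency <- function(x) x@docFreq
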