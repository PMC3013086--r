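#' Class labels of a study
#'
#' @param x A \linkS4class{BeaconExperiment}.
#' @return Character vector of per-array class labels.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Raw intensity matrix
#' @param x A \linkS4class{BeaconExperiment}.
#' @return Probe-by-array numeric matrix.
#' @export
setGeneric("rawValues", function(x) standardGeneric("rawValues"))

#' Normalized intensities in noise-SD units
#' @param x A normalized \linkS4class{BeaconExperiment}.
#' @return Probe-by-array numeric matrix.
#' @export
setGeneric("normalizedValues",
           function(x) standardGeneric("normalizedValues"))

#' log10 intensities (floored noise-SD units)
#' @param x A normalized \linkS4class{BeaconExperiment}.
#' @return Probe-by-array numeric matrix.
#' @export
setGeneric("logValues", function(x) standardGeneric("logValues"))

#' Expression-call mask
#' @param x A normalized \linkS4class{BeaconExperiment}.
#' @return Probe-by-array logical matrix (TRUE = expressed).
#' @export
setGeneric("expressedMask", function(x) standardGeneric("expressedMask"))

#' Per-array fitted noise models
#' @param x A normalized \linkS4class{BeaconExperiment}.
#' @return data.frame with columns \code{array_id}, \code{noise_mean},
#'   \code{noise_sd}.
#' @export
setGeneric("noiseModels", function(x) standardGeneric("noiseModels"))

#' Per-array alignment parameters
#' @param x An aligned \linkS4class{BeaconExperiment}.
#' @return data.frame with columns \code{array_id}, \code{slope},
#'   \code{intercept} of the robust regression onto the reference
#'   pseudo-array.
#' @export
setGeneric("alignmentParams",
           function(x) standardGeneric("alignmentParams"))

#' Planted truth of a simulated study
#' @param x A simulated \linkS4class{BeaconExperiment}.
#' @return \code{truthExpressed}: character vector of expressed probe
#'   ids; \code{truthDe}: named numeric vector of planted linear fold
#'   changes.
#' @export
setGeneric("truthExpressed", function(x) standardGeneric("truthExpressed"))

#' @rdname truthExpressed
#' @export
setGeneric("truthDe", function(x) standardGeneric("truthDe"))
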