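#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Reactivity values of an analyte matrix
#'
#' Returns the measurement matrix in the file-layout orientation: one row
#' per sample, one column per analyte. (The underlying
#' \code{SummarizedExperiment} assay stores analytes as rows, following
#' Bioconductor convention; this accessor transposes.)
#'
#' @param x An [AnalyteMatrix-class] or [BinaryMatrix-class] object.
#' @return A numeric matrix, samples x analytes.
#' @export
setGeneric("reactivity", function(x) standardGeneric("reactivity"))

#' Case/control labels
#'
#' @param x An [AnalyteMatrix-class] or [BinaryMatrix-class] object.
#' @return Integer vector, one per sample; 1 = case, 0 = control.
#' @export
setGeneric("caseLabels", function(x) standardGeneric("caseLabels"))

#' Analyte identifiers
#' @param x An [AnalyteMatrix-class] or [BinaryMatrix-class] object.
#' @return Character vector of analyte ids.
#' @export
setGeneric("analyteIds", function(x) standardGeneric("analyteIds"))

#' Sample identifiers
#' @param x An [AnalyteMatrix-class] or [BinaryMatrix-class] object.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Threshold a reactivity matrix into presence/absence indicators
#'
#' An entry becomes 1 exactly when the reactivity value strictly exceeds
#' the threshold \code{gamma} ("exceeds" is read strictly; no value on the
#' default gamma grid coincides with a measurement in practice, so strict
#' vs inclusive rarely matters, but the strict rule is the documented
#' contract).
#'
#' @param x An [AnalyteMatrix-class].
#' @param gamma Positive binarization threshold, in the same units as the
#'   reactivity values.
#' @return A [BinaryMatrix-class] carrying the indicators, the labels of
#'   \code{x}, and \code{gamma}.
#' @examples
#' b <- binarize(workedExample(), gamma = 1.4)
#' reactivity(b)
#' @export
setGeneric("binarize", function(x, gamma) standardGeneric("binarize"))
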