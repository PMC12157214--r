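#' Case/control analyte reactivity matrix
#'
#' Container for a samples x analytes matrix of non-negative reactivity
#' measurements with a binary disease label per sample. Extends
#' \code{SummarizedExperiment}: the \code{"reactivity"} assay holds
#' analytes as rows and samples as columns, and \code{colData(x)$label}
#' holds the labels (1 = case, 0 = control). Use [AnalyteMatrix()] to
#' construct one from the samples-as-rows layout used in input files.
#'
#' @slot .Data inherited \code{SummarizedExperiment} machinery.
#' @seealso [readAnalyteMatrix()], [binarize()], [simulateAnalytes()]
#' @aliases AnalyteMatrix-class
#' @export
setClass("AnalyteMatrix", contains = "SummarizedExperiment")

.validAnalyteMatrix <- function(object) {
    msg <- NULL
    if (!"reactivity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'reactivity' is required")
    else {
        v <- SummarizedExperiment::assay(object, "reactivity")
        if (!is.numeric(v)) msg <- c(msg, "reactivity values must be numeric")
        else if (any(!is.finite(v))) msg <- c(msg, "reactivity values must be finite")
        else if (any(v < 0)) msg <- c(msg, "reactivity values must be non-negative")
    }
    lab <- SummarizedExperiment::colData(object)$label
    if (is.null(lab))
        msg <- c(msg, "colData must contain a 'label' column")
    else if (!all(lab %in% c(0L, 1L)))
        msg <- c(msg, "labels must be 0 (control) or 1 (case)")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "analyte ids must be unique")
    if (ncol(object) == 0L || nrow(object) == 0L)
        msg <- c(msg, "matrix must have at least one sample and one analyte")
    if (is.null(msg)) TRUE else msg
}
setValidity("AnalyteMatrix", .validAnalyteMatrix)

#' Binarized analyte matrix
#'
#' Result of [binarize()]: a \code{SummarizedExperiment}-derived container
#' whose \code{"indicators"} assay is a 0/1 matrix (analytes x samples),
#' with the originating threshold stored in \code{metadata(x)$gamma} and
#' the sample labels carried through in \code{colData}.
#'
#' @aliases BinaryMatrix-class
#' @export
setClass("BinaryMatrix", contains = "SummarizedExperiment")

.validBinaryMatrix <- function(object) {
    msg <- NULL
    if (!"indicators" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'indicators' is required")
    else {
        v <- SummarizedExperiment::assay(object, "indicators")
        if (!all(v %in% c(0, 1))) msg <- c(msg, "indicators must be 0/1")
    }
    g <- S4Vectors::metadata(object)$gamma
    if (is.null(g) || !is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
        msg <- c(msg, "metadata gamma must be a single positive number")
    if (is.null(SummarizedExperiment::colData(object)$label))
        msg <- c(msg, "colData must contain a 'label' column")
    if (is.null(msg)) TRUE else msg
}
setValidity("BinaryMatrix", .validBinaryMatrix)

#' Per-analyte causal scoring results
#'
#' Holds, for every analyte: the s2 score (sensitivity x specificity of
#' its binarized indicator as a case-predictor), the eligibility flag
#' (s2 at least the mean s2 over all analytes), the relatedness set R_i
#' (eligible analytes co-positive with i in at least one case sample),
#' and the causal metric (mean over R_i of the pairwise measure), which is
#' NaN when the analyte is ineligible or has no related analytes.
#'
#' @slot analyteIds character, analyte identifiers.
#' @slot s2 numeric in \[0, 1\].
#' @slot eligible logical.
#' @slot related list of character vectors (ids of related analytes).
#' @slot causal numeric in \[-1, 1\] or NaN.
#' @slot gamma numeric(1), binarization threshold used.
#' @slot variant character(1), pair-measure variant used.
#' @seealso [causalScores()], [rankCausal()]
#' @aliases CausalScoreSet-class
#' @export
setClass("CausalScoreSet",
    representation(analyteIds = "character", s2 = "numeric",
                   eligible = "logical", related = "list",
                   causal = "numeric", gamma = "numeric",
                   variant = "character"))

setValidity("CausalScoreSet", function(object) {
    n <- length(object@analyteIds)
    msg <- NULL
    if (length(object@s2) != n || length(object@eligible) != n ||
        length(object@related) != n || length(object@causal) != n)
        msg <- c(msg, "per-analyte slots must have equal length")
    if (any(object@s2 < 0 | object@s2 > 1))
        msg <- c(msg, "s2 values must lie in [0, 1]")
    ok <- !is.nan(object@causal)
    if (any(ok & (object@causal < -1 | object@causal > 1)))
        msg <- c(msg, "defined causal values must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CausalScoreSet-class compact display.
#' @param object a \code{CausalScoreSet}.
#' @export
setMethod("show", "CausalScoreSet", function(object) {
    cat("CausalScoreSet:", length(object@analyteIds), "analytes, gamma =",
        object@gamma, ", variant =", object@variant, "\n")
    cat("  eligible:", sum(object@eligible),
        "| defined causal scores:", sum(!is.nan(object@causal)), "\n")
    df <- scoreTable(object)
    print(utils::head(df, 8))
    if (nrow(df) > 8) cat("  ...", nrow(df) - 8, "more analytes\n")
})

#' Per-analyte univariate chi-square scores
#'
#' @slot analyteIds character.
#' @slot chi2 numeric, non-negative; NaN for degenerate (all-zero total)
#'   analytes, which rank last.
#' @seealso [chi2Scores()], [rankUnivariate()]
#' @aliases UnivariateScoreSet-class
#' @export
setClass("UnivariateScoreSet",
    representation(analyteIds = "character", chi2 = "numeric"))

setValidity("UnivariateScoreSet", function(object) {
    if (length(object@analyteIds) != length(object@chi2))
        return("analyteIds and chi2 must have equal length")
    ok <- !is.nan(object@chi2)
    if (any(object@chi2[ok] < 0)) return("chi2 scores must be non-negative")
    TRUE
})

#' @describeIn UnivariateScoreSet-class compact display.
#' @param object a \code{UnivariateScoreSet}.
#' @export
setMethod("show", "UnivariateScoreSet", function(object) {
    cat("UnivariateScoreSet:", length(object@analyteIds), "analytes\n")
    ord <- rankUnivariate(object)
    top <- utils::head(ord, 5)
    cat("  top:", paste(top, collapse = ", "), "\n")
})

#' Classifier specification
#'
#' One of five classifier families with its hyperparameters and seed.
#' Construct with [modelSpec()], which fills in the package defaults
#' for each family.
#'
#' @slot kind character(1): "LR", "RF", "MLP", "GBT" or "XGB".
#' @slot params named list of hyperparameters.
#' @slot seed integer(1) random seed.
#' @aliases ModelSpec-class
#' @export
setClass("ModelSpec",
    representation(kind = "character", params = "list", seed = "integer"))

setValidity("ModelSpec", function(object) {
    if (!object@kind %in% c("LR", "RF", "MLP", "GBT", "XGB"))
        return("kind must be one of LR, RF, MLP, GBT, XGB")
    TRUE
})

#' @describeIn ModelSpec-class compact display.
#' @param object a \code{ModelSpec}.
#' @export
setMethod("show", "ModelSpec", function(object) {
    ps <- paste(names(object@params),
                vapply(object@params, function(p) paste(format(p), collapse = ","),
                       character(1)),
                sep = "=", collapse = ", ")
    cat("ModelSpec<", object@kind, "> seed =", object@seed, "\n  ", ps, "\n")
})

#' Fitted classifier on a selected panel
#'
#' @slot kind character(1) classifier family.
#' @slot panel character, analyte ids of the selected panel (column order
#'   the model was trained with).
#' @slot fit the underlying fitted object.
#' @slot trainScores numeric, case-probabilities on the training samples.
#' @slot spec the [ModelSpec-class] used.
#' @slot center,scale numeric, per-column standardization used for the MLP
#'   (empty otherwise).
#' @aliases FittedModel-class
#' @export
setClass("FittedModel",
    representation(kind = "character", panel = "character", fit = "ANY",
                   trainScores = "numeric", spec = "ModelSpec",
                   center = "numeric", scale = "numeric"))

#' Selection and preprocessing parameters
#'
#' @slot gamma numeric(1) binarization threshold (> 0).
#' @slot k integer(1) maximum panel size (>= 1).
#' @slot method character(1): "causal" or "univariate".
#' @slot binarizeInputs logical(1): feed gamma-binarized values to the
#'   classifier (the "(B)" variants); also switches univariate scoring to
#'   the binarized matrix. Causal scoring always uses the binarized
#'   matrix regardless.
#' @slot minmaxScale logical(1): min-max scale classifier inputs and
#'   univariate scoring (fit on the training fold).
#' @aliases SelectionParams-class
#' @export
setClass("SelectionParams",
    representation(gamma = "numeric", k = "integer", method = "character",
                   binarizeInputs = "logical", minmaxScale = "logical"))

setValidity("SelectionParams", function(object) {
    msg <- NULL
    if (length(object@gamma) != 1L || !is.finite(object@gamma) || object@gamma <= 0)
        msg <- c(msg, "gamma must be a single positive number")
    if (length(object@k) != 1L || object@k < 1L)
        msg <- c(msg, "k must be a single integer >= 1")
    if (!object@method %in% c("causal", "univariate"))
        msg <- c(msg, "method must be 'causal' or 'univariate'")
    if (is.null(msg)) TRUE else msg
})

#' Leave-one-out cross-validation result
#'
#' @slot sampleIds character, held-out sample ids (fold order).
#' @slot scores numeric, pooled out-of-fold case-probabilities.
#' @slot labels integer, true labels aligned with \code{scores}.
#' @slot foldPanels list of character vectors: the panel selected in each
#'   fold (from that fold's training samples only).
#' @slot foldTrainAuc numeric, per-fold training AUC.
#' @slot testAuc,trainAuc,sen90,sen80 numeric(1) summary metrics.
#' @slot frequency named numeric, fraction of folds selecting each analyte.
#' @slot config list echoing the configuration that produced the result.
#' @aliases EvalResult-class
#' @export
setClass("EvalResult",
    representation(sampleIds = "character", scores = "numeric",
                   labels = "integer", foldPanels = "list",
                   foldTrainAuc = "numeric", testAuc = "numeric",
                   trainAuc = "numeric", sen90 = "numeric", sen80 = "numeric",
                   frequency = "numeric", config = "list"))

#' @describeIn EvalResult-class compact display.
#' @param object an \code{EvalResult}.
#' @export
setMethod("show", "EvalResult", function(object) {
    cat("EvalResult:", length(object@scores), "LOOCV folds\n")
    cat(sprintf("  test AUC %.3f | train AUC %.3f | Sen@90 %.3f | Sen@80 %.3f\n",
                object@testAuc, object@trainAuc, object@sen90, object@sen80))
    f <- sort(object@frequency[object@frequency > 0], decreasing = TRUE)
    top <- utils::head(f, 5)
    cat("  most selected:",
        paste(sprintf("%s (%.0f%%)", names(top), 100 * top), collapse = ", "), "\n")
})

#' Synthetic data generator specification
#'
#' Parameters of the case/control generator; defaults emulate the study
#' conditions of a balanced antibody-array screen: 50 cases, 50 controls,
#' 3440 analytes whose background reactivity is log-normal with median 1,
#' concentrated near 1 with sparse exceedance of the seropositivity
#' cutoff, plus a handful of planted informative analytes
#' with seropositivity-style signal (a per-sample Bernoulli presence whose
#' probability differs between cases and controls, and an elevated
#' reactivity component well above the binarization grid when present).
#'
#' @slot nCases,nControls,nAnalytes,nInformative integers.
#' @slot pCase,pControl seropositivity probabilities for informative
#'   analytes (pCase > pControl).
#' @slot backgroundMeanlog,backgroundSdlog log-normal background
#'   parameters (meanlog 0 fixes the median at 1).
#' @slot elevatedMeanlog,elevatedSdlog log-normal parameters of the
#'   seropositive component.
#' @slot seed integer(1).
#' @seealso [syntheticSpec()], [simulateAnalytes()]
#' @aliases SyntheticSpec-class
#' @export
setClass("SyntheticSpec",
    representation(nCases = "integer", nControls = "integer",
                   nAnalytes = "integer", nInformative = "integer",
                   pCase = "numeric", pControl = "numeric",
                   backgroundMeanlog = "numeric", backgroundSdlog = "numeric",
                   elevatedMeanlog = "numeric", elevatedSdlog = "numeric",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- NULL
    if (object@nCases < 1L || object@nControls < 1L)
        msg <- c(msg, "need at least one case and one control")
    if (object@nInformative > object@nAnalytes || object@nInformative < 0L)
        msg <- c(msg, "nInformative must lie in [0, nAnalytes]")
    if (!(object@pControl >= 0 && object@pControl < object@pCase &&
          object@pCase <= 1))
        msg <- c(msg, "need 0 <= pControl < pCase <= 1")
    if (is.null(msg)) TRUE else msg
})
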