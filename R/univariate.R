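#' Chi-square univariate association scores
#'
#' The ablation baseline: for each analyte, the per-class sums of its
#' (non-negative) values are compared with the sums expected from the
#' class proportions, O_c = sum of values in class c, E_c = total x
#' n_c / n, and the score is sum over classes of (O_c - E_c)^2 / E_c
#' (the feature-selection convention for non-negative features; 1 degree
#' of freedom, higher score = stronger association = lower p). On a 0/1
#' binarized matrix this reduces to the classic 2x2 count chi-square
#' without continuity correction. Analytes with a zero total are
#' degenerate and score NaN; they rank last.
#'
#' @param x an [AnalyteMatrix-class] (raw values) or
#'   [BinaryMatrix-class] (the "(B)" variant).
#' @param values optional samples x analytes matrix overriding the values
#'   in \code{x} (used internally for min-max scaled scoring).
#' @return A [UnivariateScoreSet-class].
#' @export
chi2Scores <- function(x, values = NULL) {
    labels <- caseLabels(x)
    v <- if (is.null(values)) reactivity(x) else values
    if (any(v < 0)) stop("chi-square scoring requires non-negative values")
    nCase <- sum(labels == 1)
    nCtrl <- sum(labels == 0)
    if (nCase == 0L || nCtrl == 0L)
        stop("labels must contain at least one case and one control")
    n <- nCase + nCtrl
    o1 <- colSums(v[labels == 1, , drop = FALSE])
    o0 <- colSums(v[labels == 0, , drop = FALSE])
    tot <- o1 + o0
    e1 <- tot * nCase / n
    e0 <- tot * nCtrl / n
    chi2 <- (o1 - e1)^2 / e1 + (o0 - e0)^2 / e0
    chi2[tot == 0] <- NaN
    new("UnivariateScoreSet", analyteIds = colnames(v), chi2 = unname(chi2))
}

#' Rank analytes by chi-square score
#'
#' Descending by score; ties broken by analyte position ascending;
#' degenerate (NaN) analytes last.
#'
#' @param us a [UnivariateScoreSet-class].
#' @return Character vector of analyte ids, best first.
#' @export
rankUnivariate <- function(us) {
    if (all(is.nan(us@chi2))) stop("all chi-square scores are degenerate")
    key <- us@chi2
    key[is.nan(key)] <- -Inf
    us@analyteIds[order(-key, seq_along(key))]
}

#' Export univariate scores as TSV
#' @param us a [UnivariateScoreSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportUnivariateScores <- function(us, path) {
    ord <- rankUnivariate(us)
    df <- data.frame(analyte_id = us@analyteIds, chi2 = us@chi2,
                     rank = match(us@analyteIds, ord),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}
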