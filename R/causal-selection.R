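#' s2 score: sensitivity times specificity of a binary indicator
#'
#' Treats the 0/1 indicator vector as a predictor of case status and
#' returns (TP / #cases) x (TN / #controls). Both factors lie in
#' \[0, 1\], so the product does too; an all-zero indicator scores 0
#' (sensitivity 0, specificity 1) and an indicator identical to the
#' labels scores 1.
#'
#' @param indicator 0/1 vector, one entry per sample.
#' @param labels 0/1 vector (1 = case), same length.
#' @return numeric(1) in \[0, 1\].
#' @examples
#' s2Score(c(0, 1, 0, 1), c(0, 1, 1, 0))  # 0.25
#' @export
s2Score <- function(indicator, labels) {
    stopifnot(length(indicator) == length(labels))
    nCase <- sum(labels == 1)
    nCtrl <- sum(labels == 0)
    if (nCase == 0L || nCtrl == 0L)
        stop("labels must contain at least one case and one control")
    sens <- sum(indicator == 1 & labels == 1) / nCase
    spec <- sum(indicator == 0 & labels == 0) / nCtrl
    sens * spec
}

#' Eligibility gate: analytes scoring at least the mean s2
#'
#' The comparison is inclusive (>=): an analyte whose s2 equals the mean
#' is eligible. With all s2 equal, every analyte is eligible.
#'
#' @param s2 numeric vector of per-analyte s2 scores.
#' @return logical vector.
#' @export
eligibleSet <- function(s2) {
    if (length(s2) == 0L) stop("need at least one analyte")
    s2 >= mean(s2)
}

#' Relatedness sets via case-sample co-occurrence
#'
#' Analyte j is related to analyte i when both are eligible, i != j, and
#' at least one case sample is indicator-positive for both. The relation
#' is symmetric by construction.
#'
#' @param b a [BinaryMatrix-class] (carries indicators and labels).
#' @param eligible logical per-analyte eligibility flags; computed from
#'   the indicators when NULL.
#' @return Named list (one element per analyte) of character vectors of
#'   related analyte ids.
#' @export
relatedness <- function(b, eligible = NULL) {
    stopifnot(is(b, "BinaryMatrix"))
    ind <- reactivity(b)                       # samples x analytes
    labels <- caseLabels(b)
    if (is.null(eligible)) {
        s2 <- apply(ind, 2, s2Score, labels = labels)
        eligible <- eligibleSet(s2)
    }
    stopifnot(length(eligible) == ncol(ind))
    caseInd <- ind[labels == 1, , drop = FALSE]
    co <- crossprod(caseInd) > 0               # co-positivity in >=1 case
    diag(co) <- FALSE
    co[!eligible, ] <- FALSE
    co[, !eligible] <- FALSE
    ids <- colnames(ind)
    out <- lapply(seq_along(ids), function(i) ids[co[, i]])
    names(out) <- ids
    out
}

#' Pairwise causal contribution of analyte i given related analyte j
#'
#' Returns f(i, j) - f(not-i, j) for one ordered pair, where f composes
#' the two indicators into a single case-predictor and scores it with
#' [s2Score()]. Variants:
#' \describe{
#'   \item{"or" (default)}{f(a, j) = s2(not-a OR j); the contribution is
#'     s2(not-i OR j) - s2(i OR j). This composition reproduces the
#'     package's worked example exactly and is the reference definition.}
#'   \item{"and"}{s2(i AND j) - s2(not-i AND j).}
#'   \item{"conditional"}{s2 of i restricted to samples with j = 1 minus
#'     s2 of i restricted to samples with j = 0; NaN when either
#'     restriction lacks a case or a control.}
#' }
#'
#' @param i,j analyte ids or column indices, i != j.
#' @param b a [BinaryMatrix-class].
#' @param variant "or", "and" or "conditional".
#' @return numeric(1) in \[-1, 1\] (possibly NaN for "conditional").
#' @export
pairMeasure <- function(i, j, b, variant = c("or", "and", "conditional")) {
    variant <- match.arg(variant)
    ind <- reactivity(b)
    labels <- caseLabels(b)
    bi <- ind[, i]
    bj <- ind[, j]
    if (identical(i, j)) stop("i and j must differ")
    switch(variant,
        or = s2Score(pmax(1 - bi, bj), labels) -
             s2Score(pmax(bi, bj), labels),
        and = s2Score(bi * bj, labels) - s2Score((1 - bi) * bj, labels),
        conditional = {
            restricted <- function(sub) {
                if (!any(labels[sub] == 1) || !any(labels[sub] == 0))
                    return(NaN)
                s2Score(bi[sub], labels[sub])
            }
            restricted(bj == 1) - restricted(bj == 0)
        })
}

#' Causal metric for every analyte
#'
#' Full scoring pipeline on a case/control matrix: gamma-binarize,
#' compute per-analyte s2, gate on mean s2, build relatedness sets from
#' case-sample co-occurrence among eligible analytes, then average the
#' pairwise measure over each relatedness set:
#' causal(i) = sum over j in R_i of (f(i,j) - f(not-i,j)) / |R_i|.
#' Analytes that are ineligible or have an empty R_i get NaN. Per-analyte
#' results are independent of evaluation order; the default "or" variant
#' is computed by a vectorized path (pairwise composite counts from four
#' analyte x analyte cross-products) that is bit-identical to evaluating
#' [pairMeasure()] pair by pair.
#'
#' @param x an [AnalyteMatrix-class] or an already-binarized
#'   [BinaryMatrix-class].
#' @param gamma binarization threshold (ignored with a warning if \code{x}
#'   is already binarized).
#' @param variant pair-measure variant, see [pairMeasure()].
#' @return A [CausalScoreSet-class].
#' @examples
#' causalScores(workedExample(), gamma = 1.4)
#' @export
causalScores <- function(x, gamma = 1.4,
                         variant = c("or", "and", "conditional")) {
    variant <- match.arg(variant)
    if (is(x, "AnalyteMatrix")) {
        b <- binarize(x, gamma)
    } else if (is(x, "BinaryMatrix")) {
        b <- x
        gamma <- gammaThreshold(b)
    } else stop("x must be an AnalyteMatrix or BinaryMatrix")
    ind <- reactivity(b)
    labels <- caseLabels(b)
    nCase <- sum(labels == 1)
    nCtrl <- sum(labels == 0)
    if (nCase == 0L || nCtrl == 0L)
        stop("labels must contain at least one case and one control")
    ids <- colnames(ind)
    n <- length(ids)

    caseInd <- ind[labels == 1, , drop = FALSE]
    ctrlInd <- ind[labels == 0, , drop = FALSE]
    sens <- colSums(caseInd) / nCase
    spec <- colSums(1 - ctrlInd) / nCtrl
    s2 <- sens * spec
    eligible <- eligibleSet(s2)

    co <- crossprod(caseInd) > 0
    diag(co) <- FALSE
    co[!eligible, ] <- FALSE
    co[, !eligible] <- FALSE
    related <- lapply(seq_len(n), function(i) ids[co[, i]])
    names(related) <- ids

    causal <- rep(NaN, n)
    if (variant == "or") {
        # s2(not-i OR j): the composite is 0 only where i=1 & j=0, so the
        # case/control counts come from crossprod(B, 1-B) blocks.
        aCase <- crossprod(caseInd, 1 - caseInd)   # [i,j] cases with i=1, j=0
        aCtrl <- crossprod(ctrlInd, 1 - ctrlInd)
        zCase <- crossprod(1 - caseInd)            # co-absence counts
        zCtrl <- crossprod(1 - ctrlInd)
        fNot <- ((nCase - aCase) / nCase) * (aCtrl / nCtrl)  # s2(not-i OR j)
        fOr  <- ((nCase - zCase) / nCase) * (zCtrl / nCtrl)  # s2(i OR j)
        contrib <- fNot - fOr
        for (i in seq_len(n)) {
            r <- which(co[, i])
            if (length(r)) causal[i] <- mean(contrib[i, r])
        }
    } else {
        for (i in seq_len(n)) {
            r <- related[[i]]
            if (length(r))
                causal[i] <- mean(vapply(r, function(j)
                    pairMeasure(ids[i], j, b, variant = variant),
                    numeric(1)))
        }
    }

    new("CausalScoreSet", analyteIds = ids, s2 = unname(s2),
        eligible = unname(eligible), related = related, causal = causal,
        gamma = gamma, variant = variant)
}

#' Tabulate a CausalScoreSet
#'
#' @param cs a [CausalScoreSet-class].
#' @return data.frame with columns analyte_id, s2, eligible, n_related,
#'   causal.
#' @export
scoreTable <- function(cs) {
    data.frame(analyte_id = cs@analyteIds, s2 = cs@s2,
               eligible = cs@eligible,
               n_related = lengths(cs@related), causal = cs@causal,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Export causal scores as TSV
#' @param cs a [CausalScoreSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportScores <- function(cs, path) {
    utils::write.table(scoreTable(cs), path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Rank analytes by the causal metric
#'
#' Analytes with NaN causal scores are excluded. The rest are ordered by
#' absolute causal score descending — the metric's magnitude measures the
#' strength of the average change, and the worked example's pick order
#' requires magnitude ordering — with ties broken by s2 descending, then
#' by analyte position ascending so the ranking is deterministic.
#'
#' @param cs a [CausalScoreSet-class].
#' @return Character vector of analyte ids, best first.
#' @export
rankCausal <- function(cs) {
    ok <- which(!is.nan(cs@causal))
    if (length(ok) == 0L) stop("all causal scores are NaN; nothing to rank")
    ord <- ok[order(-abs(cs@causal[ok]), -cs@s2[ok], ok)]
    cs@analyteIds[ord]
}

#' Take the top K analytes of a ranking
#'
#' @param ranked character vector from [rankCausal()] or
#'   [rankUnivariate()].
#' @param k desired panel size (>= 1). When fewer than \code{k} ranked
#'   analytes exist the whole ranking is returned with a warning.
#' @return Character vector of at most \code{k} analyte ids.
#' @export
selectTopK <- function(ranked, k) {
    if (length(ranked) == 0L) stop("empty ranking")
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (length(ranked) < k)
        warning("only ", length(ranked), " valid analytes for k = ", k)
    utils::head(ranked, k)
}
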