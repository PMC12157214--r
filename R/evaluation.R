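#' Construct selection/preprocessing parameters
#'
#' @param gamma binarization threshold (> 0); the study grid is
#'   \{0.6, 1.0, 1.4, 1.8\} with 1.4 typically best.
#' @param k maximum panel size; the study grid is \{1, 3, 4, 10, 15, 30\}.
#' @param method "causal" or "univariate".
#' @param binarizeInputs feed gamma-binarized values to the classifier
#'   (and score the univariate statistic on them) — the "(B)" variants.
#'   Causal selection always scores the binarized matrix either way.
#' @param minmaxScale min-max scale classifier inputs and univariate
#'   scoring jointly (fit on the training fold).
#' @return A [SelectionParams-class].
#' @export
selectionParams <- function(gamma = 1.4, k = 3,
                            method = c("causal", "univariate"),
                            binarizeInputs = FALSE, minmaxScale = FALSE) {
    new("SelectionParams", gamma = gamma, k = as.integer(k),
        method = match.arg(method), binarizeInputs = binarizeInputs,
        minmaxScale = minmaxScale)
}

# Panel selection on (training) data only. Returns character panel.
selectPanel <- function(train, params) {
    if (params@method == "causal") {
        cs <- causalScores(train, gamma = params@gamma)
        ranked <- rankCausal(cs)
    } else {
        us <- if (params@binarizeInputs) {
            chi2Scores(binarize(train, params@gamma))
        } else if (params@minmaxScale) {
            chi2Scores(train, values = minmaxApply(reactivity(train),
                                                   minmaxFit(reactivity(train))))
        } else {
            chi2Scores(train)
        }
        ranked <- rankUnivariate(us)
    }
    suppressWarnings(selectTopK(ranked, params@k))
}

# Classifier input matrix (samples x analytes) under the preprocessing
# flags; scaling parameters come from the training rows only.
classifierInputs <- function(x, params, trainIdx) {
    v <- reactivity(x)
    if (params@binarizeInputs) {
        (v > params@gamma) + 0
    } else if (params@minmaxScale) {
        minmaxApply(v, minmaxFit(v[trainIdx, , drop = FALSE]))
    } else {
        v
    }
}

#' Leave-one-out cross-validated selection + classification
#'
#' Each sample is held out once; feature selection (causal or univariate)
#' is recomputed on the remaining n - 1 samples only, the classifier is
#' trained on those samples restricted to the selected panel, and the
#' held-out sample is scored. Test metrics (AUC, Sen@90, Sen@80) are
#' computed on the n pooled out-of-fold scores; the training AUC is the
#' mean of the per-fold training AUCs.
#'
#' @param x an [AnalyteMatrix-class] with at least 4 samples and both
#'   classes present.
#' @param params a [SelectionParams-class].
#' @param spec a [ModelSpec-class].
#' @param verbose print per-fold progress.
#' @return An [EvalResult-class].
#' @export
loocvRun <- function(x, params, spec, verbose = FALSE) {
    stopifnot(is(x, "AnalyteMatrix"), is(params, "SelectionParams"),
              is(spec, "ModelSpec"))
    labels <- caseLabels(x)
    n <- length(labels)
    if (n < 4L) stop("need at least 4 samples for LOOCV")
    if (length(unique(labels)) < 2L) stop("both classes must be present")

    scores <- numeric(n)
    panels <- vector("list", n)
    trainAucs <- numeric(n)
    for (s in seq_len(n)) {
        trainIdx <- setdiff(seq_len(n), s)
        trainLab <- labels[trainIdx]
        if (length(unique(trainLab)) < 2L)
            stop("fold ", s, ": training set lost a class")
        train <- subsetSamples(x, trainIdx)
        panel <- selectPanel(train, params)
        inputs <- classifierInputs(x, params, trainIdx)
        xt <- inputs[trainIdx, panel, drop = FALSE]
        model <- fitModel(spec, xt, trainLab)
        scores[s] <- predictScore(model, inputs[s, panel, drop = FALSE])
        panels[[s]] <- panel
        trainAucs[s] <- aucScore(model@trainScores, trainLab)
        if (verbose)
            message(sprintf("fold %d/%d: held out %s, score %.3f", s, n,
                            sampleIds(x)[s], scores[s]))
    }
    freq <- selectionFrequency(panels, analyteIds(x))
    new("EvalResult", sampleIds = sampleIds(x), scores = scores,
        labels = unname(labels), foldPanels = panels,
        foldTrainAuc = trainAucs,
        testAuc = aucScore(scores, labels), trainAuc = mean(trainAucs),
        sen90 = sensAtSpec(scores, labels, 0.9),
        sen80 = sensAtSpec(scores, labels, 0.8),
        frequency = freq,
        config = list(gamma = params@gamma, k = params@k,
                      method = params@method,
                      binarize_inputs = params@binarizeInputs,
                      minmax_scale = params@minmaxScale,
                      model = spec@kind, model_seed = spec@seed))
}

#' ROC operating points by exhaustive threshold enumeration
#'
#' Every distinct score value is used as a threshold (predict case when
#' score >= threshold), plus the degenerate all-negative point, giving a
#' monotone sequence from (0, 0) to (1, 1).
#'
#' @param scores numeric case-probabilities (or any ranking scores).
#' @param labels 0/1 vector.
#' @return data.frame with columns fpr, tpr, threshold (threshold Inf for
#'   the (0, 0) point).
#' @export
rocPoints <- function(scores, labels) {
    labels <- as.integer(labels)
    nP <- sum(labels == 1)
    nN <- sum(labels == 0)
    if (nP == 0L || nN == 0L) stop("both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    y <- labels[ord]
    tp <- cumsum(y)
    fp <- cumsum(1 - y)
    last <- !duplicated(s, fromLast = TRUE)   # last index of each score value
    data.frame(fpr = c(0, fp[last] / nN), tpr = c(0, tp[last] / nP),
               threshold = c(Inf, s[last]))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [rocPoints()]; equals the pairwise concordance
#' probability with ties counted one half.
#'
#' @inheritParams rocPoints
#' @return numeric(1) in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
    p <- rocPoints(scores, labels)
    sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' Sensitivity at a fixed specificity
#'
#' Maximum sensitivity over the achievable operating points whose
#' specificity is at least \code{specTarget}; no interpolation between
#' points, so a degenerate score vector yields 0.
#'
#' @inheritParams rocPoints
#' @param specTarget required specificity in (0, 1), e.g. 0.9 for Sen@90.
#' @return numeric(1) in \[0, 1\].
#' @export
sensAtSpec <- function(scores, labels, specTarget) {
    stopifnot(specTarget > 0, specTarget < 1)
    p <- rocPoints(scores, labels)
    ok <- (1 - p$fpr) >= specTarget
    max(p$tpr[ok])
}

#' Bootstrap confidence band around a ROC curve
#'
#' Class-stratified percentile bootstrap: samples are resampled with
#' replacement within cases and within controls, each resample's ROC is
#' evaluated (as a step function) on the point-estimate curve's FPR grid,
#' and pointwise quantiles at level 1 - alpha form the band.
#'
#' @inheritParams rocPoints
#' @param alpha band error level (0.05 for a 95 percent band).
#' @param nBoot number of resamples (>= 100).
#' @param seed integer seed; identical seeds give identical bands.
#' @return data.frame with columns fpr, tpr (point estimate), lower,
#'   upper.
#' @export
rocBand <- function(scores, labels, alpha = 0.05, nBoot = 1000, seed = 1) {
    if (nBoot < 100) stop("nBoot must be >= 100")
    labels <- as.integer(labels)
    pt <- rocPoints(scores, labels)
    grid <- unique(pt$fpr)
    iCase <- which(labels == 1)
    iCtrl <- which(labels == 0)
    stepTpr <- function(p, at) {
        # ROC step function: best tpr among points with fpr <= at
        vapply(at, function(f) max(p$tpr[p$fpr <= f + 1e-12]), numeric(1))
    }
    mat <- withSeed(seed, {
        vapply(seq_len(nBoot), function(b) {
            idx <- c(sample(iCase, replace = TRUE),
                     sample(iCtrl, replace = TRUE))
            stepTpr(rocPoints(scores[idx], labels[idx]), grid)
        }, numeric(length(grid)))
    })
    data.frame(fpr = grid, tpr = stepTpr(pt, grid),
               lower = apply(mat, 1, stats::quantile, probs = alpha / 2),
               upper = apply(mat, 1, stats::quantile, probs = 1 - alpha / 2))
}

#' Fraction of folds selecting each analyte
#'
#' @param folds list of per-fold panels (character vectors), e.g.
#'   \code{foldPanels} of an [EvalResult-class].
#' @param ids analyte ids to tabulate over.
#' @return Named numeric vector of per-analyte fractions in \[0, 1\].
#' @export
selectionFrequency <- function(folds, ids) {
    if (length(folds) == 0L) stop("need at least one fold")
    counts <- table(factor(unlist(folds), levels = ids))
    f <- as.numeric(counts) / length(folds)
    names(f) <- ids
    f
}

#' Relative increase in case probability given panel presence
#'
#' Binarizes the panel analytes at \code{gamma}, defines presence of the
#' panel in a sample as all (default) or any of the panel indicators
#' being positive, and returns the relative change of the case
#' probability under that condition, in percent:
#' 100 x (P(case | presence) - P(case)) / P(case).
#'
#' @param x an [AnalyteMatrix-class].
#' @param gamma binarization threshold.
#' @param panel character vector of analyte ids.
#' @param mode "all" or "any".
#' @return numeric(1) percent change (positive when presence enriches
#'   cases; -100 when presence occurs only in controls).
#' @export
probabilityIncrease <- function(x, gamma, panel, mode = c("all", "any")) {
    mode <- match.arg(mode)
    if (length(panel) == 0L) stop("empty panel")
    ind <- reactivity(binarize(x, gamma))[, panel, drop = FALSE]
    present <- if (mode == "all") rowSums(ind) == ncol(ind)
               else rowSums(ind) > 0
    if (!any(present))
        stop("no sample shows panel presence; probability increase undefined")
    labels <- caseLabels(x)
    pCase <- mean(labels == 1)
    pCond <- mean(labels[present] == 1)
    100 * (pCond - pCase) / pCase
}

#' Confusion matrix at an operating threshold
#'
#' @inheritParams rocPoints
#' @param threshold classify case when score >= threshold; defaults to
#'   the Sen@90 operating point (the smallest threshold whose specificity
#'   is at least 0.9).
#' @return 2x2 integer matrix with rows = truth (control, case) and
#'   columns = prediction (control, case).
#' @export
confusionCounts <- function(scores, labels, threshold = NULL) {
    labels <- as.integer(labels)
    if (is.null(threshold)) {
        p <- rocPoints(scores, labels)
        ok <- p[(1 - p$fpr) >= 0.9, ]
        threshold <- ok$threshold[which.max(ok$tpr)]
    }
    pred <- as.integer(scores >= threshold)
    m <- matrix(0L, 2, 2,
                dimnames = list(truth = c("control", "case"),
                                predicted = c("control", "case")))
    for (t in 0:1) for (q in 0:1)
        m[t + 1L, q + 1L] <- sum(labels == t & pred == q)
    m
}

#' Sweep the selection x classifier configuration grid
#'
#' Runs [loocvRun()] for every combination of the supplied grids and
#' collects one row per configuration (the study's full grid of 5
#' classifiers x \{causal, univariate\} x \{raw, binarized\} yields 20
#' rows). Per-cell errors are recorded in the \code{error} column rather
#' than aborting the grid; an optional checkpoint file makes interrupted
#' sweeps resumable.
#'
#' @param x an [AnalyteMatrix-class].
#' @param gammas,ks numeric grids of thresholds and panel sizes.
#' @param methods character subset of c("causal", "univariate").
#' @param kinds character subset of c("LR", "RF", "MLP", "GBT", "XGB").
#' @param binarizeFlags logical grid for classifier-input binarization.
#' @param minmaxScale logical(1) applied to every cell.
#' @param checkpointPath optional CSV path; completed rows are appended
#'   as they finish and are skipped on rerun.
#' @param verbose print one line per completed cell.
#' @return data.frame with columns model, method, binarized, gamma, k,
#'   train_auc, test_auc, sen90, sen80, error.
#' @export
sweepGrid <- function(x, gammas = 1.4, ks = 3,
                      methods = c("causal", "univariate"),
                      kinds = c("LR", "RF", "MLP", "GBT", "XGB"),
                      binarizeFlags = c(FALSE, TRUE), minmaxScale = FALSE,
                      checkpointPath = NULL, verbose = FALSE) {
    grid <- expand.grid(model = kinds, method = methods,
                        binarized = binarizeFlags, gamma = gammas, k = ks,
                        stringsAsFactors = FALSE)
    key <- function(g) paste(g$model, g$method, g$binarized, g$gamma, g$k,
                             sep = "|")
    done <- NULL
    if (!is.null(checkpointPath) && file.exists(checkpointPath)) {
        done <- utils::read.csv(checkpointPath, stringsAsFactors = FALSE)
    }
    rows <- vector("list", nrow(grid))
    for (r in seq_len(nrow(grid))) {
        g <- grid[r, ]
        if (!is.null(done) && key(g) %in% key(done)) {
            rows[[r]] <- done[key(done) == key(g), , drop = FALSE][1, ]
            next
        }
        row <- data.frame(g, train_auc = NA_real_, test_auc = NA_real_,
                          sen90 = NA_real_, sen80 = NA_real_,
                          error = "", stringsAsFactors = FALSE)
        res <- tryCatch({
            params <- selectionParams(gamma = g$gamma, k = g$k,
                                      method = g$method,
                                      binarizeInputs = g$binarized,
                                      minmaxScale = minmaxScale)
            ev <- loocvRun(x, params, modelSpec(g$model))
            row$train_auc <- ev@trainAuc
            row$test_auc <- ev@testAuc
            row$sen90 <- ev@sen90
            row$sen80 <- ev@sen80
            row
        }, error = function(e) {
            row$error <- conditionMessage(e)
            row
        })
        rows[[r]] <- res
        if (!is.null(checkpointPath))
            utils::write.table(res, checkpointPath, sep = ",",
                               row.names = FALSE, quote = TRUE,
                               col.names = !file.exists(checkpointPath),
                               append = file.exists(checkpointPath))
        if (verbose)
            message(sprintf("[%d/%d] %s/%s%s: test AUC %s", r, nrow(grid),
                            g$model, g$method,
                            if (g$binarized) "(B)" else "",
                            format(res$test_auc, digits = 3)))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
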