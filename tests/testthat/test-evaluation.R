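test_that("rocPoints enumerates all thresholds with proper endpoints", {
    labels <- c(1, 0, 1, 0, 1, 0)
    scores <- c(0.9, 0.1, 0.8, 0.4, 0.3, 0.2)
    p <- rocPoints(scores, labels)
    expect_equal(p$fpr[1], 0)
    expect_equal(p$tpr[1], 0)
    expect_equal(p$fpr[nrow(p)], 1)
    expect_equal(p$tpr[nrow(p)], 1)
    expect_true(all(diff(p$tpr) >= 0))
    expect_true(all(diff(p$fpr) >= 0))
    expect_equal(nrow(p), length(unique(scores)) + 1)

    # perfect classifier passes through (0, 1)
    pp <- rocPoints(labels, labels)
    expect_true(any(pp$fpr == 0 & pp$tpr == 1))
    # constant scores give only the two endpoints
    pc <- rocPoints(rep(0.5, 6), labels)
    expect_equal(nrow(pc), 2)
    expect_error(rocPoints(scores, rep(1, 6)), "both classes")
})

test_that("auc equals the O(n^2) concordance oracle on random instances", {
    set.seed(2024)
    for (r in 1:60) {
        n <- sample(6:60, 1)
        labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
        scores <- if (r %% 3 == 0) round(runif(n), 1) else runif(n)  # ties
        expect_equal(aucScore(scores, labels), oracleAuc(scores, labels),
                     tolerance = 1e-12)
    }
    expect_equal(aucScore(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1.0)
    expect_equal(aucScore(c(1, 0, 0, 1), c(0, 1, 1, 0)), 0.0)
})

test_that("auc agrees with pROC on a spot check", {
    skip_if_not_installed("pROC")
    set.seed(5)
    labels <- rbinom(40, 1, 0.5)
    labels[1:2] <- c(0, 1)
    scores <- runif(40)
    expect_equal(aucScore(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE))))
})

test_that("auc symmetry: auc(s) + auc(-s) = 1 for tie-free scores", {
    set.seed(77)
    for (r in 1:10) {
        labels <- c(0, 1, rbinom(18, 1, 0.5))
        scores <- rnorm(20)
        expect_equal(aucScore(scores, labels) + aucScore(-scores, labels), 1)
    }
})

test_that("sensAtSpec matches exhaustive enumeration and is monotone", {
    set.seed(11)
    for (r in 1:60) {
        n <- sample(6:40, 1)
        labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
        scores <- round(runif(n), 2)
        for (tgt in c(0.6, 0.8, 0.9))
            expect_equal(sensAtSpec(scores, labels, tgt),
                         oracleSensAtSpec(scores, labels, tgt))
        # non-increasing in the specificity target
        vals <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95), function(t)
            sensAtSpec(scores, labels, t), numeric(1))
        expect_true(all(diff(vals) <= 0))
    }
    labels <- rep(c(1, 0), 4)
    expect_equal(sensAtSpec(labels, labels, 0.9), 1.0)   # perfect separation
    expect_equal(sensAtSpec(rep(0.3, 8), labels, 0.9), 0.0)  # degenerate
})

test_that("rocBand is deterministic, contains the estimate, shrinks with n", {
    set.seed(42)
    mk <- function(n) {
        labels <- rep(c(1, 0), each = n / 2)
        scores <- plogis(rnorm(n, mean = labels))
        list(s = scores, y = labels)
    }
    d <- mk(50)
    b1 <- rocBand(d$s, d$y, nBoot = 200, seed = 9)
    b2 <- rocBand(d$s, d$y, nBoot = 200, seed = 9)
    expect_identical(b1, b2)
    expect_true(all(b1$lower <= b1$tpr + 1e-12))
    expect_true(all(b1$upper >= b1$tpr - 1e-12))
    d2 <- mk(200)
    b3 <- rocBand(d2$s, d2$y, nBoot = 200, seed = 9)
    expect_lt(mean(b3$upper - b3$lower), mean(b1$upper - b1$lower))
    expect_error(rocBand(d$s, d$y, nBoot = 50), ">= 100")
})

test_that("selectionFrequency counts panel memberships per fold", {
    folds <- list(c("a", "b"), c("a", "c"), c("a", "b"))
    f <- selectionFrequency(folds, c("a", "b", "c", "d"))
    expect_equal(unname(f), c(1, 2 / 3, 1 / 3, 0))
    # each fold contributes exactly |panel| memberships
    expect_equal(sum(f) * length(folds), sum(lengths(folds)))
    expect_error(selectionFrequency(list(), "a"), "at least one")
})

test_that("probabilityIncrease matches hand computations", {
    # presence in exactly the 2 cases of a 4-sample toy: +100%
    v <- matrix(c(5, 5, 0.1, 0.1), ncol = 1, dimnames = list(NULL, "A1"))
    m <- AnalyteMatrix(v, labels = c(1, 1, 0, 0))
    expect_equal(probabilityIncrease(m, 1.4, "A1"), 100)
    # presence in all samples: 0
    m2 <- AnalyteMatrix(matrix(rep(5, 4), ncol = 1,
                               dimnames = list(NULL, "A1")),
                        labels = c(1, 1, 0, 0))
    expect_equal(probabilityIncrease(m2, 1.4, "A1"), 0)
    # presence only in controls: -100
    m3 <- AnalyteMatrix(v, labels = c(0, 0, 1, 1))
    expect_equal(probabilityIncrease(m3, 1.4, "A1"), -100)
    # any vs all on a two-analyte panel
    v4 <- cbind(A1 = c(5, 0.1, 0.1, 0.1), A2 = c(5, 5, 0.1, 0.1))
    m4 <- AnalyteMatrix(v4, labels = c(1, 1, 0, 0))
    expect_equal(probabilityIncrease(m4, 1.4, c("A1", "A2"), mode = "all"),
                 100)                                   # only sample 1
    expect_equal(probabilityIncrease(m4, 1.4, c("A1", "A2"), mode = "any"),
                 100)                                   # samples 1, 2
    expect_error(probabilityIncrease(m, 1.4, character(0)), "empty panel")
    m5 <- AnalyteMatrix(matrix(rep(0.1, 4), ncol = 1,
                               dimnames = list(NULL, "A1")),
                        labels = c(1, 1, 0, 0))
    expect_error(probabilityIncrease(m5, 1.4, "A1"), "undefined")
})

test_that("confusionCounts matches a hand count", {
    labels <- c(1, 1, 0, 0, 1, 0)
    scores <- c(0.9, 0.4, 0.2, 0.6, 0.8, 0.1)
    m <- confusionCounts(scores, labels, threshold = 0.5)
    expect_equal(m["case", "case"], 2L)       # TP: 0.9, 0.8
    expect_equal(m["case", "control"], 1L)    # FN: 0.4
    expect_equal(m["control", "case"], 1L)    # FP: 0.6
    expect_equal(m["control", "control"], 2L)
    # perfect scores at 0.5: off-diagonal zeros
    p <- confusionCounts(labels, labels, threshold = 0.5)
    expect_equal(p["case", "control"] + p["control", "case"], 0L)
    # all scores above threshold: FN = TN = 0
    a <- confusionCounts(rep(0.9, 6), labels, threshold = 0.5)
    expect_equal(a["case", "control"] + a["control", "control"], 0L)
    # default threshold is the Sen@90 operating point
    d <- confusionCounts(scores, labels)
    spec <- d["control", "control"] / sum(d["control", ])
    expect_gte(spec, 0.9)
})

test_that("loocvRun yields one fold per sample and valid metrics", {
    sim <- simulateAnalytes(syntheticSpec(nCases = 5, nControls = 5,
                                          nAnalytes = 40, nInformative = 3,
                                          seed = 2))
    ev <- loocvRun(sim$matrix, selectionParams(k = 3), modelSpec("LR"))
    expect_length(ev@scores, 10)
    expect_length(ev@foldPanels, 10)
    expect_true(all(lengths(ev@foldPanels) <= 3))
    for (v in c(ev@testAuc, ev@trainAuc, ev@sen90, ev@sen80))
        expect_true(v >= 0 && v <= 1)
    expect_true(all(ev@frequency >= 0 & ev@frequency <= 1))
    # frequency table consistency with recorded panels
    expect_equal(sum(ev@frequency) * 10, sum(lengths(ev@foldPanels)))
    # minimum-size input (n = 4) runs under univariate selection
    ev4 <- loocvRun(workedExample(),
                    selectionParams(k = 1, method = "univariate"),
                    modelSpec("LR"))
    expect_length(ev4@scores, 4)
})

test_that("fold panels are reproducible from training samples alone", {
    sim <- simulateAnalytes(syntheticSpec(nCases = 6, nControls = 6,
                                          nAnalytes = 50, nInformative = 3,
                                          seed = 4))
    params <- selectionParams(k = 2, method = "causal")
    ev <- loocvRun(sim$matrix, params, modelSpec("LR"))
    n <- length(ev@scores)
    for (s in c(1, 4, n)) {
        train <- subsetSamples(sim$matrix, setdiff(seq_len(n), s))
        panel <- suppressWarnings(
            selectTopK(rankCausal(causalScores(train, params@gamma)),
                       params@k))
        expect_identical(ev@foldPanels[[s]], panel)
    }
})

test_that("loocvRun is deterministic and respects preconditions", {
    sim <- simulateAnalytes(syntheticSpec(nCases = 4, nControls = 4,
                                          nAnalytes = 30, nInformative = 2,
                                          seed = 6))
    params <- selectionParams(k = 2, method = "univariate")
    a <- loocvRun(sim$matrix, params, modelSpec("RF"))
    b <- loocvRun(sim$matrix, params, modelSpec("RF"))
    expect_identical(a@scores, b@scores)
    tiny <- AnalyteMatrix(matrix(1:6 / 10, 3, 2), labels = c(1, 0, 1))
    expect_error(loocvRun(tiny, params, modelSpec("LR")), "at least 4")
})

test_that("sweep covers the grid, records errors, and resumes", {
    sim <- simulateAnalytes(syntheticSpec(nCases = 6, nControls = 6,
                                          nAnalytes = 25, nInformative = 3,
                                          pCase = 0.9, pControl = 0.05,
                                          seed = 8))
    tab <- sweepGrid(sim$matrix, kinds = c("LR", "XGB"),
                     methods = "univariate", binarizeFlags = FALSE)
    expect_equal(nrow(tab), 2)
    expect_true(all(tab$error == ""))
    # single-cell grid
    one <- sweepGrid(sim$matrix, kinds = "LR", methods = "causal",
                     binarizeFlags = FALSE)
    expect_equal(nrow(one), 1)
    # determinism
    one2 <- sweepGrid(sim$matrix, kinds = "LR", methods = "causal",
                      binarizeFlags = FALSE)
    expect_identical(one, one2)
    # resume from a checkpoint reproduces the uninterrupted table
    ck <- withr::local_tempfile(fileext = ".csv")
    full <- sweepGrid(sim$matrix, kinds = c("LR", "XGB"),
                      methods = "univariate", binarizeFlags = FALSE,
                      checkpointPath = ck)
    resumed <- sweepGrid(sim$matrix, kinds = c("LR", "XGB"),
                         methods = "univariate", binarizeFlags = FALSE,
                         checkpointPath = ck)
    expect_equal(resumed[names(resumed) != "error"],
                 full[names(full) != "error"])
})
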