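# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.defaultParams <- list(
    LR  = list(),
    RF  = list(ntree = 10),
    MLP = list(size = 32, decay = 1e-4, maxit = 300),
    GBT = list(max_depth = 2, learning_rate = 1.0, nrounds = 10,
               reg_lambda = 0, tree_method = "exact"),
    XGB = list(max_depth = 2, learning_rate = 1.0, nrounds = 10))

.defaultSeed <- c(LR = 0L, RF = 0L, MLP = 1L, GBT = 0L, XGB = 0L)

#' Construct a classifier specification
#'
#' Five classifier families share one train/score contract:
#' \describe{
#'   \item{LR}{logistic regression (iteratively reweighted least squares,
#'     the standard quasi-Newton GLM fit).}
#'   \item{RF}{random forest, 10 trees.}
#'   \item{MLP}{feed-forward neural network (single hidden layer of 32
#'     logistic units, weight decay 1e-4, inputs standardized, iteration
#'     cap 300 so runs terminate deterministically).}
#'   \item{GBT}{gradient-boosted trees: depth 2, learning rate 1.0,
#'     10 rounds, exact greedy splits, no L2 regularization.}
#'   \item{XGB}{XGBoost: depth 2, learning rate 1.0, 10 rounds, library
#'     defaults otherwise.}
#' }
#' Defaults can be overridden through \code{...}; \code{seed} defaults to
#' 1 for MLP and 0 for the others.
#'
#' @param kind "LR", "RF", "MLP", "GBT" or "XGB".
#' @param ... hyperparameter overrides merged over the defaults.
#' @param seed integer random seed for this model.
#' @return A [ModelSpec-class].
#' @examples
#' modelSpec("XGB")
#' @export
modelSpec <- function(kind = c("LR", "RF", "MLP", "GBT", "XGB"), ...,
                      seed = NULL) {
    kind <- match.arg(kind)
    params <- utils::modifyList(.defaultParams[[kind]], list(...))
    if (is.null(seed)) seed <- .defaultSeed[[kind]]
    new("ModelSpec", kind = kind, params = params, seed = as.integer(seed))
}

#' Fit a classifier on a selected panel
#'
#' @param spec a [ModelSpec-class].
#' @param x numeric matrix, samples x panel analytes, with column names.
#' @param labels 0/1 vector (1 = case).
#' @return A [FittedModel-class]; its training scores are
#'   case-probabilities in \[0, 1\].
#' @export
fitModel <- function(spec, x, labels) {
    stopifnot(is(spec, "ModelSpec"))
    x <- as.matrix(x)
    if (ncol(x) == 0L) stop("empty panel")
    if (is.null(colnames(x))) stop("panel columns must be named")
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2L)
        stop("training labels must contain both classes")
    p <- spec@params
    center <- numeric(0)
    scl <- numeric(0)
    fit <- switch(spec@kind,
        LR = {
            f <- suppressWarnings(
                stats::glm.fit(cbind(1, x), labels,
                               family = stats::binomial()))
            cf <- f$coefficients
            cf[is.na(cf)] <- 0
            cf
        },
        RF = withSeed(spec@seed,
            randomForest::randomForest(x, factor(labels, levels = c(0, 1)),
                                       ntree = p$ntree)),
        MLP = {
            center <- colMeans(x)
            scl <- apply(x, 2, stats::sd)
            scl[scl == 0] <- 1
            xs <- scale(x, center = center, scale = scl)
            withSeed(spec@seed,
                nnet::nnet(xs, labels, size = p$size, decay = p$decay,
                           maxit = p$maxit, entropy = TRUE, trace = FALSE,
                           MaxNWts = 1e5))
        },
        GBT = ,
        XGB = {
            dm <- xgboost::xgb.DMatrix(x, label = labels, nthread = 1)
            extra <- p[setdiff(names(p), "nrounds")]
            pars <- do.call(xgboost::xgb.params, c(list(
                objective = "binary:logistic", nthread = 1,
                seed = spec@seed), extra))
            xgboost::xgb.train(params = pars, data = dm,
                               nrounds = p$nrounds, verbose = 0)
        })
    model <- new("FittedModel", kind = spec@kind, panel = colnames(x),
                 fit = fit, trainScores = numeric(0), spec = spec,
                 center = center, scale = scl)
    model@trainScores <- predictScore(model, x)
    model
}

#' Score samples with a fitted model
#'
#' Columns of \code{x} are aligned to the model's panel by analyte id, so
#' a column-permuted input with matching names scores identically.
#'
#' @param model a [FittedModel-class].
#' @param x numeric matrix containing (at least) the panel's named
#'   columns.
#' @return Numeric vector of case-probabilities in \[0, 1\], one per row
#'   of \code{x}.
#' @export
predictScore <- function(model, x) {
    x <- as.matrix(x)
    if (is.null(colnames(x)))
        stop("input columns must be named with analyte ids")
    missing <- setdiff(model@panel, colnames(x))
    if (length(missing))
        stop("input lacks panel analyte(s): ", paste(missing, collapse = ", "))
    x <- x[, model@panel, drop = FALSE]
    out <- switch(model@kind,
        LR = stats::plogis(drop(cbind(1, x) %*% model@fit)),
        RF = stats::predict(model@fit, x, type = "prob")[, "1"],
        MLP = {
            xs <- scale(x, center = model@center, scale = model@scale)
            drop(stats::predict(model@fit, xs))
        },
        GBT = ,
        XGB = stats::predict(model@fit,
                             xgboost::xgb.DMatrix(x, nthread = 1)))
    out <- as.numeric(out)
    pmin(pmax(out, 0), 1)
}
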