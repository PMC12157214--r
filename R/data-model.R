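#' Construct an AnalyteMatrix from a samples x analytes matrix
#'
#' @param values numeric matrix, one row per sample, one column per
#'   analyte; all entries finite and non-negative.
#' @param labels per-sample labels, coercible to integer 0/1
#'   (1 = case, 0 = control).
#' @param sampleIds,analyteIds identifiers; taken from the dimnames of
#'   \code{values} when present, generated (\code{S1..}, \code{A1..})
#'   otherwise.
#' @return An [AnalyteMatrix-class].
#' @examples
#' m <- AnalyteMatrix(matrix(rexp(20), 5, 4), labels = c(1, 1, 0, 0, 1))
#' reactivity(m)
#' @export
AnalyteMatrix <- function(values, labels, sampleIds = NULL, analyteIds = NULL) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("reactivity values must be numeric")
    if (is.null(sampleIds)) sampleIds <- rownames(values)
    if (is.null(analyteIds)) analyteIds <- colnames(values)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(values)))
    if (is.null(analyteIds)) analyteIds <- paste0("A", seq_len(ncol(values)))
    labels <- as.integer(labels)
    if (length(labels) != nrow(values))
        stop("need exactly one label per sample")
    a <- t(values)
    dimnames(a) <- list(as.character(analyteIds), as.character(sampleIds))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(reactivity = a),
        colData = S4Vectors::DataFrame(label = labels,
                                       row.names = as.character(sampleIds)))
    new("AnalyteMatrix", se)
}

#' @rdname reactivity
#' @export
setMethod("reactivity", "AnalyteMatrix", function(x)
    t(SummarizedExperiment::assay(x, "reactivity")))

#' @rdname reactivity
#' @export
setMethod("reactivity", "BinaryMatrix", function(x)
    t(SummarizedExperiment::assay(x, "indicators")))

#' @rdname caseLabels
#' @export
setMethod("caseLabels", "SummarizedExperiment", function(x) {
    lab <- as.integer(SummarizedExperiment::colData(x)$label)
    names(lab) <- colnames(x)
    lab
})

#' @rdname analyteIds
#' @export
setMethod("analyteIds", "SummarizedExperiment", function(x) rownames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))

#' Binarization threshold of a BinaryMatrix
#' @param x a [BinaryMatrix-class].
#' @return numeric(1), the gamma used.
#' @export
gammaThreshold <- function(x) S4Vectors::metadata(x)$gamma

#' @rdname binarize
#' @export
setMethod("binarize", "AnalyteMatrix", function(x, gamma) {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
        gamma <= 0)
        stop("gamma must be a single positive number")
    ind <- (SummarizedExperiment::assay(x, "reactivity") > gamma) + 0
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(indicators = ind),
        colData = SummarizedExperiment::colData(x),
        metadata = list(gamma = gamma))
    new("BinaryMatrix", se)
})

#' Min-max scale each analyte to \[0, 1\]
#'
#' Each analyte column is mapped by (x - min) / (max - min) over the
#' samples. Constant analytes (max == min) map to all zeros, which avoids
#' a division by zero and keeps them uninformative downstream.
#'
#' @param x an [AnalyteMatrix-class].
#' @return An [AnalyteMatrix-class] with scaled values.
#' @export
minmaxScale <- function(x) {
    stopifnot(is(x, "AnalyteMatrix"))
    v <- reactivity(x)
    p <- minmaxFit(v)
    AnalyteMatrix(minmaxApply(v, p), labels = caseLabels(x),
                  sampleIds = sampleIds(x), analyteIds = analyteIds(x))
}

# Per-column min/range estimated on one matrix so the identical map can be
# applied to held-out samples without leaking their values.
minmaxFit <- function(v) {
    lo <- apply(v, 2, min)
    hi <- apply(v, 2, max)
    rng <- hi - lo
    rng[rng == 0] <- Inf   # constant column -> maps to 0
    list(lo = lo, rng = rng)
}

minmaxApply <- function(v, fit) {
    out <- sweep(sweep(v, 2, fit$lo, "-"), 2, fit$rng, "/")
    pmax(out, 0)  # held-out values below the training minimum clamp at 0
}

#' Read a case/control analyte matrix from a delimited text file
#'
#' Expects one row per sample with a header of analyte ids, a designated
#' label column, and (optionally) a sample-id column, by default the first
#' column when it is non-numeric. The delimiter is auto-detected between
#' comma and tab unless given.
#'
#' @param path file path.
#' @param labelColumn name of the label column (default \code{"label"}).
#'   It must contain exactly two level codes: either 0/1 already, the
#'   strings "case"/"control", or two levels with \code{caseLevel} naming
#'   the case.
#' @param sampleIdColumn name of the sample-id column, or NULL to use the
#'   first column when it is non-numeric.
#' @param delimiter "," or "\t"; NULL (default) auto-detects.
#' @param caseLevel value in the label column to map to 1 (case).
#' @return An [AnalyteMatrix-class].
#' @export
readAnalyteMatrix <- function(path, labelColumn = "label",
                              sampleIdColumn = NULL, delimiter = NULL,
                              caseLevel = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(delimiter)) {
        first <- readLines(path, n = 1L)
        delimiter <- if (grepl("\t", first)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = delimiter,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
    if (nrow(df) == 0L) stop("empty matrix: no sample rows in ", path)
    if (!labelColumn %in% names(df))
        stop("missing label column '", labelColumn, "'")
    if (is.null(sampleIdColumn) && !is.numeric(df[[1L]]) &&
        names(df)[1L] != labelColumn)
        sampleIdColumn <- names(df)[1L]
    if (!is.null(sampleIdColumn)) {
        if (!sampleIdColumn %in% names(df))
            stop("missing sample-id column '", sampleIdColumn, "'")
        sampleIds <- as.character(df[[sampleIdColumn]])
        if (anyDuplicated(sampleIds)) stop("duplicate sample ids")
    } else {
        sampleIds <- paste0("S", seq_len(nrow(df)))
    }
    labels <- .mapLabels(df[[labelColumn]], caseLevel)
    keep <- setdiff(names(df), c(labelColumn, sampleIdColumn))
    if (length(keep) == 0L) stop("empty matrix: no analyte columns")
    vals <- df[keep]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad))
        stop("non-numeric measurement column(s): ",
             paste(keep[bad], collapse = ", "))
    v <- as.matrix(vals)
    if (any(!is.finite(v))) stop("non-finite measurement values")
    if (any(v < 0)) stop("negative measurement values")
    AnalyteMatrix(v, labels = labels, sampleIds = sampleIds,
                  analyteIds = keep)
}

.mapLabels <- function(raw, caseLevel = NULL) {
    lev <- unique(raw)
    if (length(lev) != 2L)
        stop("label column must contain exactly two level codes, found ",
             length(lev))
    if (!is.null(caseLevel)) {
        if (!caseLevel %in% lev) stop("caseLevel not present in label column")
        return(as.integer(raw == caseLevel))
    }
    if (is.numeric(raw) && all(raw %in% c(0, 1))) return(as.integer(raw))
    low <- tolower(as.character(raw))
    if (all(low %in% c("case", "control"))) return(as.integer(low == "case"))
    stop("cannot map labels {", paste(lev, collapse = ", "),
         "} to case/control; pass caseLevel")
}

#' Write an analyte matrix to a delimited text file
#'
#' Columns: \code{sample_id}, \code{label}, then one column per analyte.
#' Values are written with 17 significant digits so a
#' write/[readAnalyteMatrix()] round trip reproduces them bit-for-bit.
#'
#' @param x an [AnalyteMatrix-class].
#' @param path output path.
#' @param delimiter "," (default) or "\t".
#' @return \code{path}, invisibly.
#' @export
writeAnalyteMatrix <- function(x, path, delimiter = ",") {
    v <- reactivity(x)
    chr <- apply(v, 2, function(col) sprintf("%.17g", col))
    if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(v))
    df <- data.frame(sample_id = sampleIds(x), label = caseLabels(x),
                     chr, check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("sample_id", "label", analyteIds(x))
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Subset an analyte matrix to a set of samples
#'
#' @param x an [AnalyteMatrix-class].
#' @param samples integer, logical or character index of samples to keep.
#' @return An [AnalyteMatrix-class] with the selected samples.
#' @export
subsetSamples <- function(x, samples) {
    new("AnalyteMatrix", as(x, "SummarizedExperiment")[, samples])
}
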