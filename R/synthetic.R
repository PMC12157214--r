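#' Construct a synthetic generator specification
#'
#' Defaults emulate a balanced antibody-array case/control screen:
#' 50 cases and 50 controls over 3440 analytes whose background
#' reactivity is log-normal with median 1 (meanlog 0) and a right tail
#' (sdlog 0.3): most background values sit near 1 and only ~1 percent
#' exceed the seropositivity cutoff of 2, matching the sparse
#' seropositivity of normalized protein-array data.
#' Informative analytes carry seropositivity-style signal: a
#' per-sample Bernoulli presence with probability \code{pCase} in cases
#' and \code{pControl} in controls, and, when present, a reactivity drawn
#' from an elevated log-normal component (median 4 — above the
#' seropositivity cutoff of 2 and the binarization grid).
#'
#' @param nCases,nControls,nAnalytes,nInformative sample and analyte
#'   counts.
#' @param pCase,pControl seropositivity probabilities
#'   (0 <= pControl < pCase <= 1).
#' @param backgroundMeanlog,backgroundSdlog background log-normal
#'   parameters.
#' @param elevatedMeanlog,elevatedSdlog seropositive-component
#'   parameters.
#' @param seed integer seed; identical specs give identical matrices.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nCases = 50, nControls = 50, nAnalytes = 3440,
                          nInformative = 5, pCase = 0.8, pControl = 0.1,
                          backgroundMeanlog = 0, backgroundSdlog = 0.3,
                          elevatedMeanlog = log(4), elevatedSdlog = 0.5,
                          seed = 1) {
    new("SyntheticSpec", nCases = as.integer(nCases),
        nControls = as.integer(nControls), nAnalytes = as.integer(nAnalytes),
        nInformative = as.integer(nInformative), pCase = pCase,
        pControl = pControl, backgroundMeanlog = backgroundMeanlog,
        backgroundSdlog = backgroundSdlog, elevatedMeanlog = elevatedMeanlog,
        elevatedSdlog = elevatedSdlog, seed = as.integer(seed))
}

#' Generate a synthetic case/control analyte matrix
#'
#' Background analytes are i.i.d. log-normal, independent of the label.
#' Each informative analyte (positions drawn at random) is seropositive
#' per sample with class-dependent probability; seropositive entries draw
#' from the elevated component, seronegative entries from the background.
#' The planted analyte ids are returned separately so recovery tests
#' never leak into the pipeline.
#'
#' @param spec a [SyntheticSpec-class] (see [syntheticSpec()]).
#' @return List with elements \code{matrix} (an [AnalyteMatrix-class],
#'   cases first) and \code{informative} (character ids of the planted
#'   analytes).
#' @examples
#' sim <- simulateAnalytes(syntheticSpec(nAnalytes = 50, seed = 7))
#' sim$informative
#' @export
simulateAnalytes <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    n <- spec@nCases + spec@nControls
    labels <- c(rep(1L, spec@nCases), rep(0L, spec@nControls))
    withSeed(spec@seed, {
        v <- matrix(stats::rlnorm(n * spec@nAnalytes,
                                  spec@backgroundMeanlog,
                                  spec@backgroundSdlog),
                    nrow = n, ncol = spec@nAnalytes)
        idx <- if (spec@nInformative > 0)
            sort(sample(spec@nAnalytes, spec@nInformative)) else integer(0)
        for (j in idx) {
            p <- ifelse(labels == 1, spec@pCase, spec@pControl)
            sero <- stats::rbinom(n, 1, p) == 1
            v[sero, j] <- stats::rlnorm(sum(sero), spec@elevatedMeanlog,
                                        spec@elevatedSdlog)
        }
        ids <- paste0("A", seq_len(spec@nAnalytes))
        m <- AnalyteMatrix(v, labels = labels,
                           sampleIds = paste0("S", seq_len(n)),
                           analyteIds = ids)
        list(matrix = m, informative = ids[idx])
    })
}

#' The built-in 4-sample, 4-analyte worked example
#'
#' A small fixture used throughout the documentation and tests to
#' illustrate the causal metric end to end: four samples (labels
#' 0, 1, 1, 0) and four analytes B1..B4. Binarized at gamma = 1.4 it
#' yields s2 = (0.25, 0.25, 0.5, 0), eligibility (TRUE, TRUE, TRUE,
#' FALSE), relatedness R_B1 = \{B3\}, R_B3 = \{B1\} (empty otherwise) and
#' causal scores (0.25, NaN, -0.25, NaN), so the selection order is
#' B3 then B1. The same matrix ships as
#' \code{system.file("extdata", "worked_example.csv",
#' package = "CausalPanel")}.
#'
#' @return An [AnalyteMatrix-class], 4 samples x 4 analytes.
#' @examples
#' scoreTable(causalScores(workedExample(), gamma = 1.4))
#' @export
workedExample <- function() {
    v <- matrix(c(1.28, 3.24, 0.32, 4.56,
                  1.73, 0.21, 2.12, 1.12,
                  0.50, 1.62, 0.67, 0.45,
                  2.31, 0.82, 1.32, 3.65),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("S", 1:4),
                                c("B1", "B2", "B3", "B4")))
    AnalyteMatrix(v, labels = c(0L, 1L, 1L, 0L))
}
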