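# Independent oracles used to cross-check the package's implementations.
# Each is written as a direct, brute-force transcription of the defining
# property, deliberately sharing no code with the implementation.

# AUC as the pairwise concordance probability (ties count one half).
oracleAuc <- function(scores, labels) {
    cs <- scores[labels == 1]
    ct <- scores[labels == 0]
    tot <- 0
    for (a in cs) for (b in ct)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cs) * length(ct))
}

# Sensitivity at fixed specificity by exhaustive threshold enumeration.
oracleSensAtSpec <- function(scores, labels, target) {
    best <- 0
    for (t in c(Inf, unique(scores))) {
        pred <- as.integer(scores >= t)
        sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
        spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
        if (spec >= target) best <- max(best, sens)
    }
    best
}

# Chi-square goodness-of-fit of the per-class value totals against the
# class proportions, delegated to stats::chisq.test.
oracleChi2 <- function(values, labels) {
    o <- c(sum(values[labels == 1]), sum(values[labels == 0]))
    p <- c(mean(labels == 1), mean(labels == 0))
    if (sum(o) == 0) return(NaN)
    unname(suppressWarnings(stats::chisq.test(o, p = p)$statistic))
}

# Eligibility by literal mean comparison.
oracleEligible <- function(s2) {
    out <- logical(length(s2))
    m <- sum(s2) / length(s2)
    for (i in seq_along(s2)) out[i] <- s2[i] >= m
    out
}

# Relatedness by exhaustive (i, j, case-sample) triple enumeration on a
# samples x analytes 0/1 matrix.
oracleRelatedness <- function(ind, labels, eligible) {
    n <- ncol(ind)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        rel <- integer(0)
        for (j in seq_len(n)) {
            if (i == j || !eligible[i] || !eligible[j]) next
            hit <- FALSE
            for (s in which(labels == 1))
                if (ind[s, i] == 1 && ind[s, j] == 1) hit <- TRUE
            if (hit) rel <- c(rel, j)
        }
        out[[i]] <- rel
    }
    out
}

# Causal scores computed by the literal per-pair definition through
# pairMeasure(), mirroring the published pipeline step by step; used to
# check the vectorized path bit-for-bit.
referenceCausal <- function(b) {
    ind <- reactivity(b)
    labels <- caseLabels(b)
    s2 <- apply(ind, 2, s2Score, labels = labels)
    elig <- s2 >= mean(s2)
    ids <- colnames(ind)
    rel <- oracleRelatedness(ind, labels, elig)
    causal <- rep(NaN, length(ids))
    for (i in seq_along(ids)) {
        r <- rel[[i]]
        if (length(r))
            causal[i] <- mean(vapply(r, function(j)
                pairMeasure(ids[i], ids[j], b), numeric(1)))
    }
    causal
}

# Random small case/control matrix for property tests.
randomMatrix <- function(n = 8, p = 6, seed = 1) {
    set.seed(seed)
    labels <- c(1, rep(0:1, length.out = n - 2), 0)  # both classes always
    AnalyteMatrix(matrix(stats::rexp(n * p), n, p), labels = labels)
}
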