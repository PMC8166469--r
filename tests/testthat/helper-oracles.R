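## Independent brute-force oracles used across the suite. These are
## deliberately naive re-derivations (double loops, explicit product-limit
## accounting) kept separate from the implementation paths they check.

## Product-limit estimator by explicit accounting at each event time.
bruteKM <- function(times, events) {
    ts <- sort(unique(times[events == 1]))
    surv <- numeric(length(ts))
    s <- 1
    for (k in seq_along(ts)) {
        at_risk <- sum(times >= ts[k])
        d <- sum(times == ts[k] & events == 1)
        s <- s * (1 - d / at_risk)
        surv[k] <- s
    }
    data.frame(time = ts, survival = surv)
}

## Two-group log-rank chi-square from observed-minus-expected sums.
bruteLogrank <- function(times, events, group) {
    group <- as.integer(as.factor(group))
    ts <- sort(unique(times[events == 1]))
    O1 <- E1 <- V <- 0
    for (t in ts) {
        n <- sum(times >= t)
        n1 <- sum(times >= t & group == 1L)
        d <- sum(times == t & events == 1)
        d1 <- sum(times == t & events == 1 & group == 1L)
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O1 - E1)^2 / V
}

## Pair scoring by an explicit double loop over (pair, sample).
bruteScorePairs <- function(expr, pairs) {
    out <- matrix(NA_integer_, nrow(pairs), ncol(expr))
    for (p in seq_len(nrow(pairs)))
        for (s in seq_len(ncol(expr)))
            out[p, s] <- if (expr[pairs$gene_a[p], s] <
                             expr[pairs$gene_b[p], s]) 0L else 1L
    out
}

## Youden maximisation over all midpoints of adjacent sorted unique
## scores, for the uncensored (binary-status) case; ties toward the
## smaller threshold.
bruteYouden <- function(scores, status) {
    u <- sort(unique(scores))
    cands <- if (length(u) < 2) u else (u[-length(u)] + u[-1]) / 2
    j <- vapply(cands, function(c) {
        sens <- sum(scores > c & status == 1) / sum(status == 1)
        spec <- sum(scores <= c & status == 0) / sum(status == 0)
        sens + spec
    }, numeric(1))
    cands[which(j == max(j))[1]]
}

## Mann-Whitney AUC (ties count 1/2).
bruteAUC <- function(scores, status) {
    pos <- scores[status == 1]
    neg <- scores[status == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
}

## Expression fixture with known structure: genes x samples, gene-major
## values drawn once under a fixed seed.
makeExpr <- function(nGenes = 10, nSamples = 10, seed = 1) {
    set.seed(seed)
    matrix(rnorm(nGenes * nSamples, 5, 2), nGenes, nSamples,
           dimnames = list(paste0("G", seq_len(nGenes)),
                           paste0("S", seq_len(nSamples))))
}

## Write a small TSV and return its path.
writeTSV <- function(df, dir = tempdir(), name = "fixture.tsv") {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}
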