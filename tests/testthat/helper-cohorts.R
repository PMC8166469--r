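## Pair-score cohort with independent Bernoulli(0.5) pair scores and
## exponential survival driven by a planted subset of pairs; used by the
## model-fitting tests.
makeScoredCohort <- function(n, nPairs, planted = integer(0),
                             beta = numeric(0), seed = 1,
                             censorMax = 6000) {
    set.seed(seed)
    scores <- matrix(rbinom(nPairs * n, 1, 0.5), nPairs, n,
                     dimnames = list(NULL, sprintf("P%04d", seq_len(n))))
    psm <- PairScoreMatrix(scores,
                           gene_a = sprintf("GA%03d", seq_len(nPairs)),
                           gene_b = sprintf("GB%03d", seq_len(nPairs)))
    lp <- if (length(planted))
        as.numeric(crossprod(scores[planted, , drop = FALSE], beta))
    else rep(0, n)
    tEvent <- rexp(n, 2.5e-4 * exp(lp))
    cens <- runif(n, 0, censorMax)
    clinical <- data.frame(sample = colnames(scores),
                           os_time = pmin(tEvent, cens),
                           os_event = as.integer(tEvent <= cens),
                           age = rnorm(n, 67, 10),
                           sex = sample(c("male", "female"), n, TRUE),
                           stage = sample(c("I", "II", "III", "IV"), n,
                                          TRUE),
                           stringsAsFactors = FALSE)
    list(psm = psm, clinical = clinical)
}
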