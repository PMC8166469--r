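test_that("univariate screen keeps planted effects and respects alpha", {
    co <- makeScoredCohort(400, 30, planted = 1, beta = log(2.5), seed = 8)
    kept <- univariateScreen(co$psm, co$clinical)
    expect_true(pairNames(co$psm)[1] %in% kept)
    p <- attr(kept, "p_values")
    expect_identical(names(p), pairNames(co$psm))
    expect_lt(p[1], 0.05)

    ## alpha = 1 keeps every non-degenerate pair
    all_kept <- univariateScreen(co$psm, co$clinical, alpha = 1)
    expect_identical(length(all_kept), 30L)

    ## degenerate pairs are skipped with a warning
    sc <- pairScores(co$psm); sc[2, ] <- 1L
    degen <- PairScoreMatrix(sc, pairGenes(co$psm)$gene_a,
                             pairGenes(co$psm)$gene_b)
    expect_warning(kept2 <- univariateScreen(degen, co$clinical),
                   "constant")
    expect_false(pairNames(degen)[2] %in% kept2)

    ## wald and score tests agree on which strong pair is retained
    kept_s <- univariateScreen(co$psm, co$clinical, test = "score")
    expect_true(pairNames(co$psm)[1] %in% kept_s)
})

test_that("univariate screen has approximately nominal null retention", {
    ## 1000 pairs independent of survival: about 5% pass at alpha 0.05
    co <- makeScoredCohort(200, 1000, seed = 15)
    kept <- univariateScreen(co$psm, co$clinical)
    expect_gt(length(kept) / 1000, 0.02)
    expect_lt(length(kept) / 1000, 0.09)
})

test_that("lasso-Cox recovers planted pairs and reports selection frequencies", {
    co <- makeScoredCohort(500, 200, planted = 1:5,
                           beta = c(0.8, -0.8, 0.7, -0.7, 0.9),
                           seed = 23)
    sig <- fitLassoCox(co$psm, co$clinical, nRepeats = 5, folds = 5,
                       seed = 99)
    ids <- paste(signaturePairs(sig)$gene_a, signaturePairs(sig)$gene_b,
                 sep = "|")
    planted_ids <- pairNames(co$psm)[1:5]
    sens <- mean(planted_ids %in% ids)
    expect_gte(sens, 0.8)
    ## false-selection rate: fraction of the 195 null candidates selected
    fsr <- sum(!ids %in% planted_ids) / (200 - 5)
    expect_lte(fsr, 0.1)
    freq <- sig@metadata$selection_frequency
    expect_identical(names(freq), pairNames(co$psm))
    expect_true(all(freq[planted_ids] >= 0.8))
    expect_identical(length(sig@metadata$lambda_repeats), 5L)
})

test_that("a no-signal cohort yields no stable lasso model", {
    co <- makeScoredCohort(300, 100, seed = 37)
    res <- tryCatch(fitLassoCox(co$psm, co$clinical, nRepeats = 5,
                                folds = 5, seed = 99),
                    error = function(e) e)
    if (inherits(res, "error")) {
        expect_match(conditionMessage(res), "zero")
    } else {
        freq <- res@metadata$selection_frequency
        sel <- paste(signaturePairs(res)$gene_a,
                     signaturePairs(res)$gene_b, sep = "|")
        expect_lte(sum(freq[sel] >= 0.2), 2L)
    }
})

test_that("a single repeat reproduces one standard CV fit", {
    co <- makeScoredCohort(300, 50, planted = 1:2, beta = c(1, -1),
                           seed = 51)
    sig1 <- fitLassoCox(co$psm, co$clinical, nRepeats = 1, folds = 5,
                        seed = 7)
    set.seed(7)
    x <- t(pairScores(co$psm))
    y <- survival::Surv(co$clinical$os_time, co$clinical$os_event)
    foldid <- sample(rep_len(1:5, 300))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                            foldid = foldid)
    expect_equal(sig1@metadata$lambda, cv$lambda.min)
})

test_that("risk score is the exact published linear form", {
    sig <- loadPublishedSignature()
    p <- signaturePairs(sig)
    mk <- function(v) PairScoreMatrix(matrix(v, ncol = 1,
                                             dimnames = list(NULL, "s1")),
                                      p$gene_a, p$gene_b)
    ## all pair scores 0: empty sum
    expect_equal(riskScore(sig, mk(rep(0L, 17)))$risk_score, 0)
    ## only the CXCL14|BST2 pair active: score is its coefficient
    one <- rep(0L, 17); one[1] <- 1L
    expect_equal(riskScore(sig, mk(one))$risk_score, -0.317773355)
    ## all 17 active: the hand-computed coefficient sum
    expect_equal(riskScore(sig, mk(rep(1L, 17)))$risk_score, -1.139905958)
})

test_that("risk score is linear in the signature", {
    set.seed(61)
    expr <- makeExpr(12, 20, seed = 61)
    pairs <- enumeratePairs(rownames(expr))[1:10, ]
    b <- rnorm(10)
    sigA <- IRGPSignature(pairs$gene_a[1:4], pairs$gene_b[1:4], b[1:4])
    sigB <- IRGPSignature(pairs$gene_a[5:10], pairs$gene_b[5:10], b[5:10])
    sigAB <- IRGPSignature(pairs$gene_a, pairs$gene_b, b)
    expect_equal(riskScore(sigAB, expr)$risk_score,
                 riskScore(sigA, expr)$risk_score +
                 riskScore(sigB, expr)$risk_score)
    sig3 <- IRGPSignature(pairs$gene_a, pairs$gene_b, 3 * b)
    expect_equal(riskScore(sig3, expr)$risk_score,
                 3 * riskScore(sigAB, expr)$risk_score)
})

test_that("risk scoring from expression handles stored pair orientation", {
    sig <- loadPublishedSignature()
    set.seed(71)
    expr <- matrix(rnorm(26 * 8, 5, 2), 26, 8,
                   dimnames = list(signatureGenes(sig), paste0("s", 1:8)))
    rtE <- riskScore(sig, expr)
    ## via a lexicographic all-pairs PairScoreMatrix (orientation flips)
    psm <- scorePairs(expr, enumeratePairs(rownames(expr)))
    rtP <- riskScore(sig, psm)
    expect_equal(rtP$risk_score, rtE$risk_score)

    expect_error(riskScore(sig, expr[rownames(expr) != "CXCL14", ]),
                 "CXCL14")
    expect_error(riskScore(sig, psm[pairNames(psm) != "BST2|CXCL14", ]),
                 "CXCL14")
})

test_that("stratification is strict at the cutoff", {
    rt <- data.frame(sample = c("a", "b", "c"),
                     risk_score = c(-0.464, -0.463, -0.465))
    out <- stratifyRisk(rt, -0.464)
    expect_identical(out$group, c("low", "high", "low"))
    all_high <- stratifyRisk(rt, -1)
    expect_true(all(all_high$group == "high"))

    ## exhaustive-oracle partition with the published cutoff
    set.seed(81)
    sig <- loadPublishedSignature()
    expr <- matrix(rnorm(26 * 60, 5, 2), 26, 60,
                   dimnames = list(signatureGenes(sig), paste0("s", 1:60)))
    rt <- stratifyRisk(riskScore(sig, expr), signatureCutoff(sig))
    brute <- vapply(rt$risk_score,
                    function(s) if (s > -0.464) "high" else "low", "")
    expect_identical(rt$group, brute)
    expect_true(all(c("high", "low") %in% rt$group))
})
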