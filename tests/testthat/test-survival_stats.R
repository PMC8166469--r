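test_that("Kaplan-Meier estimate matches hand product-limit values", {
    km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
    expect_equal(km$n_risk, c(3, 2, 1))

    ## one death at t = 5 among two subjects, the other censored later
    km2 <- kmEstimate(c(5, 10), c(1, 0))
    expect_equal(kmSurvivalAt(km2, 5), 1 / 2)
    expect_equal(kmSurvivalAt(km2, 4.9), 1)

    ## censored-only data: flat S = 1
    km3 <- kmEstimate(c(2, 4, 6), c(0, 0, 0))
    expect_identical(nrow(km3), 0L)
    expect_equal(kmSurvivalAt(km3, c(0, 3, 10)), c(1, 1, 1))
})

test_that("Kaplan-Meier matches the brute-force product-limit loop", {
    set.seed(11)
    for (i in 1:10) {
        n <- sample(5:25, 1)
        times <- sample(1:12, n, replace = TRUE)  # force ties
        events <- rbinom(n, 1, 0.7)
        if (!any(events == 1)) next
        km <- kmEstimate(times, events)
        ref <- bruteKM(times, events)
        expect_equal(km$time, ref$time)
        expect_equal(km$survival, ref$survival)
    }
})

test_that("log-rank test matches the observed-minus-expected oracle", {
    ## identical survival in both groups: chi-square 0, p 1
    tt <- c(1, 2, 3, 1, 2, 3); ev <- c(1, 1, 0, 1, 1, 0)
    g <- rep(c("a", "b"), each = 3)
    r <- logrankTest(tt, ev, g)
    expect_equal(r$chi_square, 0)
    expect_equal(r$p_value, 1)

    ## six-subject example, hand-computable O-E accounting
    tt <- c(6, 13, 21, 30, 31, 38); ev <- c(1, 1, 1, 1, 0, 1)
    g <- c(0, 1, 0, 1, 0, 1)
    r <- logrankTest(tt, ev, g)
    expect_equal(r$chi_square, bruteLogrank(tt, ev, g), tolerance = 1e-10)
    expect_equal(r$p_value,
                 pchisq(r$chi_square, 1, lower.tail = FALSE))
    expect_error(logrankTest(tt, ev, rep(1, 6)), "two")
})

test_that("log-rank type-I error is calibrated under the permutation null", {
    set.seed(2026)
    n <- 60
    times <- rexp(n, 1 / 500)
    cens <- runif(n, 0, 1500)
    ev <- as.integer(times <= cens)
    tt <- pmin(times, cens)
    p <- replicate(2000, {
        g <- sample(rep(0:1, each = n / 2))
        logrankTest(tt, ev, g)$p_value
    })
    expect_equal(mean(p < 0.05), 0.05, tolerance = 0.3)
    ## p-values approximately uniform under the null
    ks <- suppressWarnings(ks.test(p, "punif"))
    expect_gt(ks$p.value, 0.001)
})

test_that("Cox score test equals the log-rank statistic for a binary covariate", {
    set.seed(5)
    for (i in 1:5) {
        n <- 80
        g <- rbinom(n, 1, 0.5)
        tt <- rexp(n, 1 / 400 * exp(0.5 * g))
        ev <- rbinom(n, 1, 0.8)
        if (length(unique(g)) < 2 || sum(ev) < 2) next
        fit <- coxFit(data.frame(g = g), tt, ev)
        lr <- logrankTest(tt, ev, g)
        expect_equal(fit$score_chisq, lr$chi_square, tolerance = 1e-6)
    }
})

test_that("Cox fit recovers a known hazard ratio and flags separation", {
    set.seed(31)
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    tEvent <- rexp(n, 2.5e-4 * exp(log(2) * x))
    cens <- runif(n, 0, 9000)   # about 30% censoring
    tt <- pmin(tEvent, cens); ev <- as.integer(tEvent <= cens)
    expect_lt(abs(mean(1 - ev) - 0.3), 0.1)
    fit <- coxFit(data.frame(x = x), tt, ev)
    expect_true(fit$converged)
    hr <- fit$table$hr[1]
    expect_gt(hr, 1.7); expect_lt(hr, 2.3)
    expect_true(fit$table$ci_low[1] <= hr && hr <= fit$table$ci_high[1])

    ## complete separation is flagged, not silent
    sep <- coxFit(data.frame(x = c(1, 1, 1, 0, 0, 0)),
                  c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1))
    expect_false(sep$converged)
    expect_error(coxFit(data.frame(x = 1:4), 1:4, rep(0, 4)), "event")
})

test_that("Cox Wald CI covers the null at nominal rate for independent covariates", {
    set.seed(77)
    cover <- replicate(500, {
        n <- 500
        x <- rnorm(n)
        tEvent <- rexp(n, 1 / 1000)
        cens <- runif(n, 0, 3000)
        fit <- coxFit(data.frame(x = x), pmin(tEvent, cens),
                      as.integer(tEvent <= cens))
        fit$table$ci_low[1] <= 1 && 1 <= fit$table$ci_high[1]
    })
    expect_equal(mean(cover), 0.95, tolerance = 0.035)
})

test_that("time-dependent ROC reduces to the Mann-Whitney AUC without censoring", {
    set.seed(13)
    for (i in 1:5) {
        n <- 60
        score <- rnorm(n)
        tt <- rexp(n, 1 / 100 * exp(0.8 * score))
        horizon <- median(tt)
        roc <- tdROC(score, tt, rep(1, n), horizon = horizon)
        expect_equal(roc$auc, bruteAUC(score, as.integer(tt <= horizon)),
                     tolerance = 1e-10)
    }
})

test_that("degenerate and perfect markers give AUC 0.5 and 1", {
    tt <- c(10, 20, 30, 40, 50, 60); ev <- rep(1, 6)
    flat <- tdROC(rep(2.5, 6), tt, ev, horizon = 35)
    expect_equal(flat$auc, 0.5)
    perfect <- tdROC(-tt, tt, ev, horizon = 35)
    expect_equal(perfect$auc, 1)
    expect_error(tdROC(-tt, tt, ev, horizon = 5), "no events")
    expect_error(tdROC(-tt, tt, ev, horizon = 100), "horizon")
})

test_that("ROC sensitivity and specificity are monotone in the threshold", {
    set.seed(21)
    for (i in 1:5) {
        n <- 100
        score <- rnorm(n)
        tEvent <- rexp(n, 1 / 300 * exp(0.5 * score))
        cens <- runif(n, 0, 800)
        tt <- pmin(tEvent, cens); ev <- as.integer(tEvent <= cens)
        roc <- tdROC(score, tt, ev, horizon = median(tt))
        expect_true(all(diff(roc$sensitivity) <= 1e-12))
        expect_true(all(diff(roc$specificity) >= -1e-12))
        expect_true(all(roc$sensitivity >= 0 & roc$sensitivity <= 1))
        expect_true(all(roc$specificity >= 0 & roc$specificity <= 1))
    }
})

test_that("Youden cutoff matches exhaustive search and breaks ties low", {
    ## perfect separation: cutoff falls between the clusters, J = 2
    score <- c(1, 2, 3, 11, 12, 13)
    tt <- c(100, 90, 80, 5, 6, 7); ev <- rep(1, 6)
    roc <- tdROC(score, tt, ev, horizon = 50)
    cut <- youdenCutoff(roc)
    expect_gt(cut, 3); expect_lt(cut, 11)
    expect_equal(max(roc$sensitivity + roc$specificity), 2)

    ## exhaustive-oracle agreement on random uncensored instances
    set.seed(41)
    for (i in 1:10) {
        n <- 40
        score <- round(rnorm(n), 1)  # ties among scores
        tEvent <- rexp(n, 1 / 50 * exp(0.7 * score))
        horizon <- median(tEvent)
        roc <- tdROC(score, tEvent, rep(1, n), horizon = horizon)
        expect_equal(youdenCutoff(roc),
                     bruteYouden(score, as.integer(tEvent <= horizon)))
    }

    ## flat (uninformative) marker: smallest candidate threshold
    score <- c(1, 1, 2, 2)
    roc0 <- tdROC(score, c(10, 50, 10, 50), rep(1, 4), horizon = 30)
    expect_equal(youdenCutoff(roc0), min(roc0$thresholds))
})
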