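## Survival machinery behind screening, cutoff selection and validation:
## Kaplan-Meier, log-rank, Cox PH (Efron ties), IPCW time-dependent ROC and
## the Youden-optimal cutoff.

#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. The returned table has
#' one row per distinct event time; with censored-only data it is empty and
#' the curve is identically 1.
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators (1 = event observed).
#' @return data.frame with columns time (ascending distinct event times),
#'   n_risk, n_event, survival.
#' @export
kmEstimate <- function(times, events) {
    stopifnot(length(times) == length(events), length(times) >= 1L,
              all(times > 0), all(events %in% c(0, 1)))
    fit <- survfit(Surv(times, events) ~ 1, conf.type = "none")
    keep <- fit$n.event > 0
    data.frame(time = fit$time[keep],
               n_risk = fit$n.risk[keep],
               n_event = fit$n.event[keep],
               survival = fit$surv[keep])
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function evaluation: S(t) is the estimate just after the last event
#' time <= t; S(0) = 1.
#'
#' @param km data.frame from [kmEstimate()].
#' @param t times at which to evaluate.
#' @return numeric vector of survival probabilities.
#' @export
kmSurvivalAt <- function(km, t) {
    vapply(t, function(ti) {
        i <- which(km$time <= ti)
        if (length(i)) km$survival[max(i)] else 1
    }, numeric(1))
}

#' Two-group log-rank test
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @param group two-level group labels (factor, character or 0/1).
#' @return list with chi_square, df (= 1) and p_value.
#' @export
logrankTest <- function(times, events, group) {
    group <- as.factor(group)
    if (nlevels(droplevels(group)) != 2L)
        stop("log-rank test needs exactly two non-empty groups")
    sd <- survdiff(Surv(times, events) ~ group)
    chisq <- unname(sd$chisq)
    list(chi_square = chisq, df = 1L,
         p_value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood with the Efron approximation for
#' ties. Categorical covariates must be pre-encoded as numeric columns.
#' Non-convergence or infinite coefficients (complete separation) are
#' flagged in \code{converged}, never silent.
#'
#' @param covariates numeric data.frame or matrix, samples x covariates.
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators; at least one event required.
#' @return list of class \code{"coxFit"}: \code{table} (per covariate:
#'   coef, hr, ci_low, ci_high, p), \code{n}, \code{n_event},
#'   \code{converged}, and \code{score_chisq} (global score test, which for
#'   a single binary covariate equals the log-rank statistic).
#' @export
coxFit <- function(covariates, times, events) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(times),
              length(times) == length(events))
    if (sum(events) < 1L) stop("Cox fit needs at least one observed event")
    dat <- cbind(data.frame(.time = times, .event = events), covariates)
    converged <- TRUE
    fit <- withCallingHandlers(
        coxph(Surv(.time, .event) ~ ., data = dat, ties = "efron"),
        warning = function(w) {
            if (grepl("converge|infinite|beta may be infinite|Loglik",
                      conditionMessage(w)))
                converged <<- FALSE
            invokeRestart("muffleWarning")
        })
    s <- summary(fit)
    if (any(!is.finite(stats::coef(fit)))) converged <- FALSE
    tab <- data.frame(covariate = names(stats::coef(fit)),
                      coef = unname(stats::coef(fit)),
                      hr = unname(s$conf.int[, "exp(coef)"]),
                      ci_low = unname(s$conf.int[, "lower .95"]),
                      ci_high = unname(s$conf.int[, "upper .95"]),
                      p = unname(s$coefficients[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
    structure(list(table = tab, n = s$n, n_event = s$nevent,
                   converged = converged,
                   score_chisq = unname(s$sctest["test"])),
              class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
    cat("Cox PH fit (Efron ties): n =", x$n, ", events =", x$n_event,
        if (!x$converged) " [NOT CONVERGED]", "\n")
    print(x$table, digits = 4)
    invisible(x)
}

## Candidate cutoffs for a marker: midpoints of adjacent sorted unique
## values (the only places the empirical ROC can change), ascending.
.candidateThresholds <- function(scores) {
    u <- sort(unique(scores))
    if (length(u) < 2L) return(u)
    (u[-length(u)] + u[-1L]) / 2
}

#' Time-dependent ROC curve for a survival marker
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon: cases are
#' subjects with an observed event at or before the horizon, controls are
#' subjects still at risk beyond it. Censoring before the horizon is
#' handled by inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution, which keeps
#' sensitivity and specificity monotone in the threshold and reduces to the
#' empirical (Mann-Whitney) ROC when no censoring occurs before the
#' horizon. A sample is called high risk when its score is strictly greater
#' than the threshold.
#'
#' @param scores numeric risk scores (higher = worse prognosis).
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @param horizon evaluation time, within the observed time range; default
#'   1825 days (5 years), the conventional horizon for colon-cancer overall
#'   survival.
#' @return list of class \code{"tdROC"}: horizon, thresholds (ascending),
#'   sensitivity, specificity, auc.
#' @export
tdROC <- function(scores, times, events, horizon = 1825) {
    stopifnot(length(scores) == length(times),
              length(times) == length(events))
    case <- times <= horizon & events == 1
    ctrl <- times > horizon
    if (!any(case))
        stop("no events observed at or before the horizon (",
             horizon, ")")
    if (!any(ctrl))
        stop("no subjects at risk beyond the horizon (", horizon,
             "); choose a horizon within the observed time range")
    ## censoring distribution G from the reversed KM; weights 1/G(T-) for
    ## cases, 1/G(horizon) for controls
    gkm <- kmEstimate(times, 1 - events)
    wg <- function(t) {
        g <- kmSurvivalAt(gkm, t)
        ifelse(g > 0, 1 / g, 0)
    }
    w <- numeric(length(scores))
    eps <- min(diff(sort(unique(c(0, times))))) / 2
    w[case] <- wg(times[case] - eps)
    w[ctrl] <- wg(horizon)
    thresholds <- .candidateThresholds(scores)
    wc <- sum(w[case]); wk <- sum(w[ctrl])
    sens <- vapply(thresholds,
                   function(c) sum(w[case & scores > c]) / wc, numeric(1))
    spec <- vapply(thresholds,
                   function(c) sum(w[ctrl & scores <= c]) / wk, numeric(1))
    fpr <- c(1, 1 - spec, 0)
    tpr <- c(1, sens, 0)
    o <- order(fpr, tpr)
    auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
    structure(list(horizon = horizon, thresholds = thresholds,
                   sensitivity = sens, specificity = spec, auc = auc),
              class = "tdROC")
}

#' @export
print.tdROC <- function(x, ...) {
    cat("Time-dependent ROC at t =", x$horizon, ": AUC =",
        format(x$auc, digits = 3), "(", length(x$thresholds),
        "thresholds )\n")
    invisible(x)
}

#' Youden-optimal cutoff from a time-dependent ROC
#'
#' The threshold with the greatest sum of sensitivity and specificity.
#' Ties are broken toward the smaller threshold (the larger high-risk
#' group), which makes the choice deterministic.
#'
#' @param roc a \code{"tdROC"} object from [tdROC()].
#' @return the optimal cutoff (one of \code{roc$thresholds}).
#' @export
youdenCutoff <- function(roc) {
    stopifnot(inherits(roc, "tdROC"), length(roc$thresholds) >= 1L)
    j <- roc$sensitivity + roc$specificity
    roc$thresholds[which(j == max(j))[1L]]
}
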