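## End-to-end orchestration: the discovery flow (gene-list intersection ->
## MAD filter -> pair scoring -> constancy filter -> univariate screen ->
## lasso-Cox -> risk scores -> ROC/Youden cutoff -> stratified survival
## analysis) and the locked-signature validation flow.

## Numeric encoding for Cox models: age in years, sex male = 1, stage
## ordinal 1-4 (unknown -> NA, dropped from multivariable fits),
## risk_group high = 1.
.encodeCovariates <- function(clinical, group) {
    data.frame(age = clinical$age,
               sex = as.numeric(clinical$sex == "male"),
               stage = match(clinical$stage, c("I", "II", "III", "IV")),
               risk_group = as.numeric(group == "high"))
}

.coxPerCovariate <- function(covariates, times, events) {
    tabs <- lapply(colnames(covariates), function(cv) {
        ok <- !is.na(covariates[[cv]])
        fit <- coxFit(covariates[ok, cv, drop = FALSE], times[ok],
                      events[ok])
        fit$table
    })
    do.call(rbind, tabs)
}

.survivalReport <- function(clinical, group) {
    enc <- .encodeCovariates(clinical, group)
    list(logrank = logrankTest(clinical$os_time, clinical$os_event, group),
         km = list(
             high = kmEstimate(clinical$os_time[group == "high"],
                               clinical$os_event[group == "high"]),
             low = kmEstimate(clinical$os_time[group == "low"],
                              clinical$os_event[group == "low"])),
         coxUnivariate = .coxPerCovariate(enc, clinical$os_time,
                                          clinical$os_event),
         coxMultivariate = coxFit(enc, clinical$os_time,
                                  clinical$os_event))
}

#' Run the discovery pipeline
#'
#' Executes the full signature-construction flow on one cohort: restrict
#' the expression matrix to immune genes, drop low-variability genes
#' (MAD filter), enumerate and score all gene pairs, remove near-constant
#' pairs, screen candidates by univariate Cox, fit the repeated-CV
#' lasso-Cox signature, compute risk scores, pick the Youden-optimal
#' cutoff on a time-dependent ROC, stratify, and run Kaplan-Meier,
#' log-rank and univariable/multivariable Cox (age, sex, stage, risk
#' group) analyses. A manifest records the candidate count after every
#' stage so the filtering funnel is auditable.
#'
#' @param expression genes x samples numeric matrix.
#' @param clinical data.frame as from [readClinical()].
#' @param geneList named list (gene -> categories) as from
#'   [readGeneList()]; only listed genes are analysed.
#' @param madThreshold MAD variability threshold (default 0.5).
#' @param maxConstantFraction constancy-filter bound (default 0.8).
#' @param screenAlpha univariate screen level (default 0.05).
#' @param folds,nRepeats lasso-Cox cross-validation settings.
#' @param rocHorizon ROC evaluation time in days (default 1825 = 5 years).
#' @param seed integer seed for the cross-validation folds.
#' @param outDir optional directory; when given, the signature (JSON),
#'   risk table, KM curves, Cox forest-plot tables and manifest (JSON) are
#'   written there.
#' @return list: signature (cutoff set), cutoff, riskTable, roc, logrank,
#'   km, coxUnivariate, coxMultivariate, clinical (aligned), manifest.
#' @export
runDiscovery <- function(expression, clinical, geneList,
                         madThreshold = 0.5, maxConstantFraction = 0.8,
                         screenAlpha = 0.05, folds = 10, nRepeats = 25,
                         rocHorizon = 1825, seed = NULL, outDir = NULL) {
    immune <- intersect(rownames(expression), names(geneList))
    if (length(immune) < 2L)
        stop("discovery aborted at gene-list intersection: fewer than two ",
             "immune genes found in the expression matrix")
    common <- intersect(colnames(expression), clinical$sample)
    if (length(common) < 30L)
        stop("discovery needs at least 30 samples shared between ",
             "expression and clinical data; found ", length(common))
    expr <- expression[immune, common, drop = FALSE]
    clin <- clinical[match(common, clinical$sample), , drop = FALSE]

    variable <- filterGenesByMAD(expr, madThreshold)
    pairs <- enumeratePairs(variable)
    psm <- scorePairs(expr, pairs)
    psm <- filterConstantPairs(psm, maxConstantFraction)
    screened <- univariateScreen(psm, clin, alpha = screenAlpha)
    if (length(screened) < 2L)
        stop("discovery aborted at the univariate screen: ",
             length(screened), " candidate pair(s) left")
    sig <- fitLassoCox(psm[screened, ], clin, nRepeats = nRepeats,
                       folds = folds, seed = seed)
    rt <- riskScore(sig, psm)
    roc <- tdROC(rt$risk_score, clin$os_time, clin$os_event,
                 horizon = rocHorizon)
    cutoff <- youdenCutoff(roc)
    rt <- stratifyRisk(rt, cutoff)
    signatureCutoff(sig) <- cutoff
    report <- .survivalReport(clin, rt$group)

    manifest <- list(
        counts = c(genes_input = nrow(expression),
                   genes_immune = length(immune),
                   genes_variable = length(variable),
                   pairs_enumerated = nrow(pairs),
                   pairs_after_constancy = nrow(psm),
                   pairs_after_screen = length(screened),
                   pairs_in_signature = length(sig)),
        n_samples = length(common), n_events = sum(clin$os_event),
        cutoff = cutoff, auc = roc$auc, seed = seed,
        config = list(madThreshold = madThreshold,
                      maxConstantFraction = maxConstantFraction,
                      screenAlpha = screenAlpha, folds = folds,
                      nRepeats = nRepeats, rocHorizon = rocHorizon))
    res <- c(list(signature = sig, cutoff = cutoff, riskTable = rt,
                  roc = roc), report,
             list(clinical = clin, manifest = manifest))
    if (!is.null(outDir)) .writeRunArtifacts(res, outDir)
    res
}

#' Validate a locked signature on a new cohort
#'
#' Scores a cohort with a fixed signature and cutoff - no refitting, no
#' imputation - then repeats the stratified survival analyses
#' (Kaplan-Meier, log-rank, univariable and multivariable Cox). By default
#' the discovery cutoff is reused unchanged, the stricter reading of
#' external validation; set \code{recomputeCutoff = TRUE} to re-derive a
#' cohort-specific Youden cutoff instead.
#'
#' @param signature an [IRGPSignature-class].
#' @param expression genes x samples matrix of the validation cohort; every
#'   signature gene must be present.
#' @param clinical validation clinical table.
#' @param cutoff risk cutoff; defaults to the signature's stored cutoff.
#' @param recomputeCutoff re-derive the cutoff on this cohort via
#'   [tdROC()] + [youdenCutoff()].
#' @param rocHorizon horizon used only when recomputing the cutoff.
#' @param outDir optional output directory, as in [runDiscovery()].
#' @return list: riskTable, cutoff, logrank, km, coxUnivariate,
#'   coxMultivariate, clinical (aligned), manifest.
#' @export
runValidation <- function(signature, expression, clinical,
                          cutoff = signatureCutoff(signature),
                          recomputeCutoff = FALSE, rocHorizon = 1825,
                          outDir = NULL) {
    stopifnot(is(signature, "IRGPSignature"))
    common <- intersect(colnames(expression), clinical$sample)
    if (!length(common))
        stop("no samples shared between expression and clinical data")
    expr <- expression[, common, drop = FALSE]
    clin <- clinical[match(common, clinical$sample), , drop = FALSE]
    rt <- riskScore(signature, expr)
    if (recomputeCutoff) {
        roc <- tdROC(rt$risk_score, clin$os_time, clin$os_event,
                     horizon = rocHorizon)
        cutoff <- youdenCutoff(roc)
    }
    if (is.na(cutoff))
        stop("no cutoff available: the signature carries none and ",
             "recomputeCutoff is FALSE")
    rt <- stratifyRisk(rt, cutoff)
    report <- .survivalReport(clin, rt$group)
    manifest <- list(n_samples = length(common),
                     n_events = sum(clin$os_event), cutoff = cutoff,
                     recomputed_cutoff = recomputeCutoff,
                     signature_pairs = length(signature))
    res <- c(list(signature = signature, cutoff = cutoff, riskTable = rt),
             report, list(clinical = clin, manifest = manifest))
    if (!is.null(outDir)) .writeRunArtifacts(res, outDir)
    res
}

.writeRunArtifacts <- function(res, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSignature(res$signature, file.path(outDir, "signature.json"))
    writeRiskTable(res$riskTable, file.path(outDir, "risk_table.tsv"))
    km <- rbind(cbind(group = "high", res$km$high),
                cbind(group = "low", res$km$low))
    utils::write.table(km, file.path(outDir, "km_curves.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(res$coxUnivariate,
                       file.path(outDir, "cox_univariate.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(res$coxMultivariate$table,
                       file.path(outDir, "cox_multivariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    invisible(outDir)
}
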