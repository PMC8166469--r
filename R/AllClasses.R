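#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' PairScoreMatrix: binary gene-pair scores per sample
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"score"},
#' with one row per gene pair and one column per sample. Entry (p, s) is 1
#' when the first gene of pair p is expressed at least as highly as the
#' second gene within sample s, and 0 otherwise. Because the score only
#' depends on the within-sample ordering of the two genes, it is invariant
#' to any strictly increasing per-sample transformation of the expression
#' values (the property that makes gene-pair signatures portable across
#' platforms).
#'
#' Row metadata carries the pair members in columns \code{gene_a} and
#' \code{gene_b}; row names are pair identifiers \code{"GENEA|GENEB"}.
#'
#' @seealso [scorePairs()], [filterConstantPairs()]
#' @export
setClass("PairScoreMatrix", contains = "SummarizedExperiment")

setValidity("PairScoreMatrix", function(object) {
    msg <- character()
    if (!"score" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'score' is required")
    else {
        sc <- SummarizedExperiment::assay(object, "score")
        if (length(sc) && !all(sc %in% c(0, 1)))
            msg <- c(msg, "scores must be 0 or 1")
    }
    rd <- rowData(object)
    if (!all(c("gene_a", "gene_b") %in% colnames(rd)))
        msg <- c(msg, "rowData must have columns gene_a and gene_b")
    else if (any(rd$gene_a == rd$gene_b))
        msg <- c(msg, "a pair cannot repeat the same gene")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "pair identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a PairScoreMatrix
#'
#' @param scores binary matrix, pairs x samples.
#' @param gene_a,gene_b character vectors naming the first and second member
#'   of each pair (one entry per row of \code{scores}).
#' @return A \linkS4class{PairScoreMatrix}.
#' @examples
#' psm <- PairScoreMatrix(matrix(c(1, 0), 1, 2,
#'                               dimnames = list(NULL, c("s1", "s2"))),
#'                        gene_a = "A", gene_b = "B")
#' pairNames(psm)
#' @export
PairScoreMatrix <- function(scores, gene_a, gene_b) {
    scores <- as.matrix(scores)
    storage.mode(scores) <- "integer"
    stopifnot(length(gene_a) == nrow(scores), length(gene_b) == nrow(scores))
    rownames(scores) <- paste(gene_a, gene_b, sep = "|")
    new("PairScoreMatrix",
        SummarizedExperiment(
            assays = list(score = scores),
            rowData = DataFrame(gene_a = as.character(gene_a),
                                gene_b = as.character(gene_b))))
}

#' @describeIn PairScoreMatrix-class pair identifiers ("GENEA|GENEB")
#' @param x,object a \code{PairScoreMatrix}
#' @export
pairNames <- function(x) rownames(x)

#' @describeIn PairScoreMatrix-class the binary score matrix
#' @export
pairScores <- function(x) SummarizedExperiment::assay(x, "score")

#' @describeIn PairScoreMatrix-class pair membership as a data.frame with
#'   columns \code{gene_a}, \code{gene_b}
#' @export
pairGenes <- function(x) {
    as.data.frame(rowData(x)[, c("gene_a", "gene_b")])
}

setMethod("show", "PairScoreMatrix", function(object) {
    cat("PairScoreMatrix:", nrow(object), "gene pairs x",
        ncol(object), "samples\n")
    frac <- if (nrow(object)) mean(pairScores(object)) else NA_real_
    cat("  overall fraction scoring 1:", format(frac, digits = 3), "\n")
})

#' IRGPSignature: a weighted gene-pair risk signature
#'
#' An ordered collection of gene pairs with lasso-Cox coefficients. The risk
#' score of a sample is the sum of coefficients over pairs whose first gene
#' is expressed at least as highly as the second in that sample. Pair
#' orientation is meaningful and preserved as stored (the published
#' colon-cancer model lists pairs in its own printed order).
#'
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{coefficient}; coefficients are finite and non-zero, pairs unique.
#' @slot cutoff numeric(1), the risk-score threshold separating high from
#'   low risk (strictly greater than the cutoff is high risk); \code{NA}
#'   until one is chosen.
#' @slot metadata list of free-form fit metadata (selection frequencies,
#'   penalty, provenance).
#' @seealso [loadPublishedSignature()], [riskScore()], [fitLassoCox()]
#' @export
setClass("IRGPSignature",
         representation(pairs = "data.frame",
                        cutoff = "numeric",
                        metadata = "list"))

setValidity("IRGPSignature", function(object) {
    p <- object@pairs
    msg <- character()
    if (!all(c("gene_a", "gene_b", "coefficient") %in% colnames(p)))
        msg <- c(msg, "pairs needs columns gene_a, gene_b, coefficient")
    else {
        if (nrow(p) < 1L) msg <- c(msg, "a signature needs at least one pair")
        if (anyDuplicated(paste(p$gene_a, p$gene_b)))
            msg <- c(msg, "signature pairs must be unique")
        if (nrow(p) && any(!is.finite(p$coefficient) | p$coefficient == 0))
            msg <- c(msg, "coefficients must be finite and non-zero")
        if (nrow(p) && any(p$gene_a == p$gene_b))
            msg <- c(msg, "a pair cannot repeat the same gene")
    }
    if (length(object@cutoff) != 1L)
        msg <- c(msg, "cutoff must be a single number (possibly NA)")
    if (length(msg)) msg else TRUE
})

#' Construct an IRGPSignature
#'
#' @param gene_a,gene_b character vectors: first and second member of each
#'   pair, in the orientation the coefficients were fitted with.
#' @param coefficient numeric vector of non-zero model coefficients.
#' @param cutoff optional risk-score cutoff (scores strictly above it are
#'   high risk).
#' @param metadata list of fit metadata.
#' @return An \linkS4class{IRGPSignature}.
#' @examples
#' sig <- IRGPSignature(gene_a = c("A", "B"), gene_b = c("C", "D"),
#'                      coefficient = c(0.5, -1.2))
#' signaturePairs(sig)
#' @export
IRGPSignature <- function(gene_a, gene_b, coefficient, cutoff = NA_real_,
                          metadata = list()) {
    new("IRGPSignature",
        pairs = data.frame(gene_a = as.character(gene_a),
                           gene_b = as.character(gene_b),
                           coefficient = as.numeric(coefficient),
                           stringsAsFactors = FALSE),
        cutoff = as.numeric(cutoff),
        metadata = metadata)
}

#' @describeIn IRGPSignature-class the pair table (gene_a, gene_b,
#'   coefficient)
#' @param object,x an \code{IRGPSignature}
#' @export
signaturePairs <- function(object) object@pairs

#' @describeIn IRGPSignature-class distinct gene symbols used by the
#'   signature
#' @export
signatureGenes <- function(object) {
    unique(c(object@pairs$gene_a, object@pairs$gene_b))
}

#' @describeIn IRGPSignature-class the stored risk-score cutoff (NA if unset)
#' @export
signatureCutoff <- function(object) object@cutoff

#' @describeIn IRGPSignature-class replace the cutoff
#' @param value new cutoff
#' @export
`signatureCutoff<-` <- function(object, value) {
    object@cutoff <- as.numeric(value)
    validObject(object)
    object
}

#' @describeIn IRGPSignature-class number of pairs
#' @export
setMethod("length", "IRGPSignature", function(x) nrow(x@pairs))

#' @describeIn IRGPSignature-class named coefficient vector
#' @param ... ignored
#' @export
setMethod("coef", "IRGPSignature", function(object, ...) {
    stats::setNames(object@pairs$coefficient,
                    paste(object@pairs$gene_a, object@pairs$gene_b, sep = "|"))
})

setMethod("show", "IRGPSignature", function(object) {
    cat("IRGPSignature:", nrow(object@pairs), "gene pairs,",
        length(signatureGenes(object)), "distinct genes\n")
    cat("  cutoff:", ifelse(is.na(object@cutoff), "unset",
                            format(object@cutoff)), "\n")
    print(utils::head(object@pairs, 5))
    if (nrow(object@pairs) > 5) cat("  ...\n")
})
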