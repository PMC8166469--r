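## Gene-pair machinery: MAD variability filter, pair enumeration, binary
## within-sample scoring, and the near-constant-pair filter.

#' Unscaled median absolute deviation
#'
#' median(|x - median(x)|) with no normal-consistency factor: the 0.5
#' variability threshold used throughout the pipeline is read against the
#' raw MAD, not the 1.4826-scaled estimator.
#'
#' @param x numeric vector, length >= 1, no missing values.
#' @return the raw MAD of \code{x}.
#' @examples
#' madRaw(1:5)  # 1
#' @export
madRaw <- function(x) {
    if (length(x) < 1L) stop("madRaw needs at least one value")
    if (anyNA(x)) stop("madRaw does not accept missing values")
    stats::mad(x, constant = 1)
}

#' Filter genes by expression variability
#'
#' Keeps genes whose raw MAD across samples is strictly greater than the
#' threshold, preserving the original gene order. Low-variability genes
#' carry little pairing information and inflate the pair space.
#'
#' @param expr numeric matrix, genes x samples.
#' @param threshold non-negative MAD threshold (default 0.5).
#' @return character vector of retained gene symbols.
#' @export
filterGenesByMAD <- function(expr, threshold = 0.5) {
    stopifnot(is.matrix(expr), threshold >= 0)
    mads <- apply(expr, 1L, madRaw)
    keep <- rownames(expr)[mads > threshold]
    if (!length(keep))
        stop("no gene exceeds MAD threshold ", threshold,
             "; consider lowering it or checking the expression scale")
    keep
}

#' Enumerate unordered gene pairs
#'
#' All n(n-1)/2 unordered pairs with a fixed lexicographic orientation
#' (gene_a < gene_b). Only one orientation per couple is kept: on tie-free
#' data the two orientations carry complementary scores, so the second adds
#' nothing.
#'
#' @param genes character vector of >= 2 unique gene symbols.
#' @return data.frame with columns gene_a, gene_b.
#' @examples
#' enumeratePairs(c("B", "A", "C"))
#' @export
enumeratePairs <- function(genes) {
    genes <- as.character(genes)
    if (anyDuplicated(genes)) stop("gene symbols must be unique")
    if (length(genes) < 2L)
        stop("need at least two genes to form a pair")
    g <- sort(genes)
    idx <- utils::combn(length(g), 2L)
    data.frame(gene_a = g[idx[1L, ]], gene_b = g[idx[2L, ]],
               stringsAsFactors = FALSE)
}

#' Score gene pairs within each sample
#'
#' For pair (a, b) and sample s the score is 0 when gene a is expressed
#' strictly lower than gene b in s, and 1 otherwise (ties score 1). The
#' score depends only on the within-sample ordering, so any strictly
#' increasing per-sample transform of the expression values leaves the
#' result unchanged.
#'
#' @param expr numeric matrix, genes x samples.
#' @param pairs data.frame with columns gene_a, gene_b (as from
#'   [enumeratePairs()]), or an [IRGPSignature-class] whose pairs should be
#'   scored in their stored orientation.
#' @return a [PairScoreMatrix-class] with samples in the order of
#'   \code{colnames(expr)}.
#' @export
scorePairs <- function(expr, pairs) {
    if (is(pairs, "IRGPSignature")) pairs <- signaturePairs(pairs)
    stopifnot(is.matrix(expr),
              all(c("gene_a", "gene_b") %in% colnames(pairs)))
    missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)),
                       rownames(expr))
    if (length(missing))
        stop("gene(s) absent from the expression matrix: ",
             paste(missing, collapse = ", "))
    a <- expr[pairs$gene_a, , drop = FALSE]
    b <- expr[pairs$gene_b, , drop = FALSE]
    scores <- matrix(as.integer(a >= b), nrow = nrow(pairs),
                     dimnames = list(NULL, colnames(expr)))
    PairScoreMatrix(scores, gene_a = pairs$gene_a, gene_b = pairs$gene_b)
}

#' Remove near-constant gene pairs
#'
#' A pair whose score is identical in more than \code{maxFraction} of the
#' samples carries almost no discriminating information. A pair is retained
#' iff its fraction of samples scoring 1 lies in
#' [1 - maxFraction, maxFraction]; the boundary is retained ("more than" is
#' strict).
#'
#' @param psm a [PairScoreMatrix-class].
#' @param maxFraction maximum tolerated constancy, in [0.5, 1) (default
#'   0.8).
#' @return the filtered [PairScoreMatrix-class].
#' @export
filterConstantPairs <- function(psm, maxFraction = 0.8) {
    stopifnot(is(psm, "PairScoreMatrix"),
              maxFraction >= 0.5, maxFraction < 1)
    frac1 <- rowMeans(pairScores(psm))
    keep <- frac1 >= 1 - maxFraction & frac1 <= maxFraction
    if (!any(keep))
        stop("all pairs are near-constant (> ", maxFraction * 100,
             "% identical scores); nothing left to analyse")
    psm[keep, ]
}
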