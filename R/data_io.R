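## Tabular I/O: expression matrices, clinical tables, immune-gene lists,
## signatures (JSON) and risk tables. All text formats are UTF-8,
## tab-delimited, '.' decimal; every writer/reader pair round-trips.

#' Read a gene-by-sample expression matrix
#'
#' Expects tab-separated text with gene symbols in the first column and a
#' header row of sample identifiers. Any monotone expression scale is
#' acceptable (CPM, log2 intensity, ...): downstream pair scoring only uses
#' within-sample orderings. Rows containing missing values are dropped with
#' a warning; duplicated gene symbols are collapsed by keeping the row with
#' the largest (unscaled) median absolute deviation, i.e. the most
#' informative measurement.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes x samples, with unique rownames.
#' @export
readExpression <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) stop("empty expression file: ", path)
    raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    if (nrow(raw) == 0L || ncol(raw) < 2L)
        stop("expression file needs a gene column plus at least one sample: ",
             path)
    samples <- colnames(raw)[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample ids in ", path, ": ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    genes <- trimws(raw[[1L]])
    if (any(genes == ""))
        stop("blank gene symbol at row(s) ",
             paste(which(genes == ""), collapse = ", "), " of ", path)
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    missing_mask <- vals == "" | is.na(vals) | toupper(vals) == "NA"
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    bad <- which(is.na(num) & !missing_mask, arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric value '", vals[bad[1L, 1L], bad[1L, 2L]],
             "' at gene ", genes[bad[1L, 1L]], ", sample ",
             samples[bad[1L, 2L]], " in ", path)
    drop <- rowSums(missing_mask) > 0L
    if (any(drop)) {
        warning(sum(drop), " gene row(s) with missing values dropped: ",
                paste(utils::head(genes[drop], 5L), collapse = ", "),
                if (sum(drop) > 5L) ", ..." else "")
        num <- num[!drop, , drop = FALSE]
        genes <- genes[!drop]
    }
    if (!nrow(num)) stop("no complete gene rows left in ", path)
    if (anyDuplicated(genes)) {
        mads <- apply(num, 1L, function(x) stats::mad(x, constant = 1))
        keep <- unlist(lapply(split(seq_along(genes), genes)[unique(genes)],
                              function(idx) idx[which.max(mads[idx])]))
        dups <- unique(genes[duplicated(genes)])
        warning("duplicate gene symbol(s) collapsed by max-MAD: ",
                paste(utils::head(dups, 5L), collapse = ", "),
                if (length(dups) > 5L) ", ..." else "")
        num <- num[sort(keep), , drop = FALSE]
        genes <- genes[sort(keep)]
    }
    dimnames(num) <- list(genes, samples)
    num
}

#' Write an expression matrix as TSV
#'
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(expr, path) {
    df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a clinical survival table
#'
#' Expects a TSV with header columns \code{sample}, \code{os_time},
#' \code{os_event}, \code{age}, \code{sex}, \code{stage}. Records with
#' missing time or event are excluded (only samples with complete survival
#' information are analysed); non-positive survival times are rejected with
#' a warning. Event coding is configurable; by default 1/"DECEASED"/"Dead"
#' map to an observed death and 0/"LIVING"/"Alive" to censoring.
#'
#' @param path path to the TSV file.
#' @param timeUnit unit of \code{os_time} in the file; months are converted
#'   to days (x 30.44). Internally all times are days.
#' @param eventCodes list with elements \code{event} and \code{censor}:
#'   accepted codings for death and censoring.
#' @return data.frame with columns sample, os_time (days), os_event (0/1),
#'   age, sex ("female"/"male"), stage ("I".."IV"/"unknown").
#' @export
readClinical <- function(path, timeUnit = c("days", "months"),
                         eventCodes = list(
                             event = c("1", "DECEASED", "Dead"),
                             censor = c("0", "LIVING", "Alive"))) {
    timeUnit <- match.arg(timeUnit)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("sample", "os_time", "os_event", "age", "sex", "stage")
    if (!all(need %in% colnames(df)))
        stop("clinical table must have columns: ",
             paste(setdiff(need, colnames(df)), collapse = ", "),
             " missing in ", path)
    blank <- function(x) is.na(x) | trimws(x) == "" | toupper(trimws(x)) == "NA"
    incomplete <- blank(df$os_time) | blank(df$os_event)
    if (any(incomplete)) {
        warning(sum(incomplete),
                " record(s) without complete survival information excluded")
        df <- df[!incomplete, , drop = FALSE]
    }
    if (!nrow(df)) stop("no records with complete survival information in ",
                        path)
    ev_raw <- trimws(df$os_event)
    ev <- ifelse(ev_raw %in% eventCodes$event, 1L,
                 ifelse(ev_raw %in% eventCodes$censor, 0L, NA_integer_))
    if (anyNA(ev))
        stop("unparseable os_event value(s): ",
             paste(unique(ev_raw[is.na(ev)]), collapse = ", "))
    time <- suppressWarnings(as.numeric(df$os_time))
    if (anyNA(time))
        stop("non-numeric os_time value(s): ",
             paste(unique(df$os_time[is.na(time)]), collapse = ", "))
    if (timeUnit == "months") time <- time * 30.44
    ok <- time > 0
    if (any(!ok)) {
        warning(sum(!ok), " record(s) with non-positive os_time rejected: ",
                paste(df$sample[!ok], collapse = ", "))
        df <- df[ok, , drop = FALSE]; ev <- ev[ok]; time <- time[ok]
    }
    sex <- tolower(trimws(df$sex))
    sex[!sex %in% c("female", "male")] <- NA_character_
    stage <- toupper(trimws(df$stage))
    stage[!stage %in% c("I", "II", "III", "IV")] <- "unknown"
    out <- data.frame(sample = trimws(df$sample),
                      os_time = time,
                      os_event = ev,
                      age = suppressWarnings(as.numeric(df$age)),
                      sex = sex,
                      stage = stage,
                      stringsAsFactors = FALSE)
    if (anyDuplicated(out$sample))
        stop("duplicate sample ids in clinical table: ",
             paste(unique(out$sample[duplicated(out$sample)]), collapse = ", "))
    out
}

#' Write a clinical survival table as TSV
#'
#' @param clinical data.frame as returned by [readClinical()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClinical <- function(clinical, path) {
    utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an immune-gene list with functional categories
#'
#' Expects a two-column TSV (header \code{symbol}, \code{category}); a
#' symbol may repeat on several rows, one per category, as in ImmPort-style
#' exports. Categories are unioned per symbol.
#'
#' @param path path to the TSV file.
#' @return named list: gene symbol -> character vector of categories.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("symbol", "category") %in% colnames(df)))
        stop("gene list needs columns 'symbol' and 'category': ", path)
    if (!nrow(df)) stop("empty gene list: ", path)
    df$symbol <- trimws(df$symbol)
    if (any(df$symbol == ""))
        stop("blank gene symbol at row(s) ",
             paste(which(df$symbol == ""), collapse = ", "), " of ", path)
    lst <- lapply(split(trimws(df$category), df$symbol), unique)
    lst[unique(df$symbol)]
}

.SIGNATURE_SCHEMA <- 1L

#' Serialize a signature to JSON
#'
#' The JSON carries a schema version, the pair table at full float
#' precision, the cutoff and all metadata, so that
#' \code{readSignature(writeSignature(x))} reproduces \code{x} exactly.
#'
#' @param sig an [IRGPSignature-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSignature <- function(sig, path) {
    stopifnot(is(sig, "IRGPSignature"))
    validObject(sig)
    obj <- list(schema_version = .SIGNATURE_SCHEMA,
                pairs = signaturePairs(sig),
                cutoff = signatureCutoff(sig),
                metadata = sig@metadata)
    ## digits = I(17): enough significant digits to reproduce any double
    ## exactly on re-read
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", null = "null", pretty = TRUE)
    invisible(path)
}

#' Read a signature from JSON
#'
#' @param path path written by [writeSignature()].
#' @return an [IRGPSignature-class].
#' @export
readSignature <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$schema_version) ||
        obj$schema_version != .SIGNATURE_SCHEMA)
        stop("unknown signature schema version: ",
             if (is.null(obj$schema_version)) "<absent>"
             else obj$schema_version)
    cutoff <- if (is.null(obj$cutoff)) NA_real_ else as.numeric(obj$cutoff)
    md <- if (is.null(obj$metadata)) list() else obj$metadata
    IRGPSignature(gene_a = obj$pairs$gene_a, gene_b = obj$pairs$gene_b,
                  coefficient = obj$pairs$coefficient,
                  cutoff = cutoff, metadata = md)
}

#' Write a risk table as TSV
#'
#' @param rt data.frame with columns \code{sample}, \code{risk_score} and
#'   (once a cutoff has been applied) \code{group}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRiskTable <- function(rt, path) {
    stopifnot(all(c("sample", "risk_score") %in% colnames(rt)))
    utils::write.table(rt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a risk table written by [writeRiskTable()]
#'
#' @param path input path.
#' @return data.frame with sample, risk_score and, if present, group.
#' @export
readRiskTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    df$sample <- as.character(df$sample)
    df
}

#' Write a PairScoreMatrix as TSV
#'
#' One row per pair (id "GENEA|GENEB"), one column per sample, 0/1 cells.
#'
#' @param psm a [PairScoreMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePairScores <- function(psm, path) {
    df <- data.frame(pair = pairNames(psm), pairScores(psm),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a PairScoreMatrix written by [writePairScores()]
#'
#' @param path input path.
#' @return a [PairScoreMatrix-class].
#' @export
readPairScores <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ab <- strsplit(df$pair, "|", fixed = TRUE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    PairScoreMatrix(m, gene_a = vapply(ab, `[`, "", 1L),
                    gene_b = vapply(ab, `[`, "", 2L))
}
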