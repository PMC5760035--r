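#' Construct an ExpressionDataset
#'
#' @param exprs numeric probe x sample matrix of log2 intensities, with
#'   row and column names.
#' @param detectionP matrix of the same shape with detection p-values in
#'   `[0, 1]`.
#' @param sampleInfo data.frame with one row per sample: `sample_id`,
#'   `region`, `time_h`, `condition` (`"treated"`/`"control"`),
#'   `animal_id`.
#' @param probeInfo data.frame with one row per probe: `probe_id`,
#'   `species`, `maturity`, `annotation` (the gene or mature-miRNA name a
#'   probe reports on; several probes may share one annotation).
#'
#' @return An [ExpressionDataset-class] object.
#' @export
ExpressionDataset <- function(exprs, detectionP, sampleInfo, probeInfo) {
    stopifnot(identical(dim(exprs), dim(detectionP)),
              nrow(sampleInfo) == ncol(exprs),
              nrow(probeInfo) == nrow(exprs))
    rownames(exprs) <- rownames(detectionP) <- probeInfo$probe_id
    colnames(exprs) <- colnames(detectionP) <- sampleInfo$sample_id
    se <- SummarizedExperiment(
        assays = list(exprs = exprs, detectionP = detectionP),
        colData = DataFrame(sampleInfo, row.names = sampleInfo$sample_id),
        rowData = DataFrame(probeInfo, row.names = probeInfo$probe_id))
    new("ExpressionDataset", se)
}

#' Accessors for ExpressionDataset
#'
#' `exprsMat` and `detectionP` return the log2-intensity and detection
#' p-value matrices; `sampleInfo` and `probeInfo` return the sample and
#' probe annotation as plain data.frames.
#'
#' @param ds An [ExpressionDataset-class].
#' @return A matrix or data.frame.
#' @export
exprsMat <- function(ds) assay(ds, "exprs")

#' @rdname exprsMat
#' @export
detectionP <- function(ds) assay(ds, "detectionP")

#' @rdname exprsMat
#' @export
sampleInfo <- function(ds) as.data.frame(colData(ds))

#' @rdname exprsMat
#' @export
probeInfo <- function(ds) as.data.frame(rowData(ds))

#' Subset an ExpressionDataset to one brain region
#'
#' All statistics in this package treat regions independently; this is the
#' canonical way to carve out one region's samples.
#'
#' @param ds An [ExpressionDataset-class].
#' @param region region label, e.g. `"AMY"`.
#' @return An [ExpressionDataset-class] holding only that region's samples.
#' @export
subsetRegion <- function(ds, region) {
    keep <- colData(ds)$region == region
    if (!any(keep))
        stop("no samples for region ", sQuote(region))
    ds[, keep]
}

#' Read / write an expression dataset as a TSV trio
#'
#' The on-disk form is three tab-separated files: the expression matrix
#' (probes x samples, first column `probe_id`), a detection p-value matrix
#' of identical shape, the sample table, and a probe table.
#'
#' @param ds An [ExpressionDataset-class].
#' @param dir directory for the four files.
#' @param prefix file-name prefix, e.g. `"mirna"`.
#' @return `writeExpressionDataset` returns the file paths invisibly;
#'   `readExpressionDataset` returns an [ExpressionDataset-class].
#' @export
writeExpressionDataset <- function(ds, dir, prefix) {
    paths <- file.path(dir, paste0(prefix, "_",
        c("exprs.tsv", "detp.tsv", "samples.tsv", "probes.tsv")))
    writeMatrixTsv(exprsMat(ds), paths[1])
    writeMatrixTsv(detectionP(ds), paths[2])
    utils::write.table(sampleInfo(ds), paths[3], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(probeInfo(ds), paths[4], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}

#' @rdname writeExpressionDataset
#' @export
readExpressionDataset <- function(dir, prefix) {
    paths <- file.path(dir, paste0(prefix, "_",
        c("exprs.tsv", "detp.tsv", "samples.tsv", "probes.tsv")))
    ex <- readMatrixTsv(paths[1])
    dp <- readMatrixTsv(paths[2])
    si <- utils::read.delim(paths[3], check.names = FALSE)
    pi <- utils::read.delim(paths[4], check.names = FALSE)
    ExpressionDataset(ex, dp, si, pi)
}

writeMatrixTsv <- function(m, path) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

readMatrixTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}
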