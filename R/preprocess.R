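#' Detect and remove outlier samples
#'
#' Within each brain region, each sample is scored by its median
#' inter-array Spearman correlation (computed over the region's mouse
#' probes when a `species` column is present, otherwise over all probes).
#' When a sample has at least three replicate arrays -- same region, time
#' and condition -- the correlations are taken against those replicates,
#' so that genuine treatment effects shared by a whole group cannot drag
#' the group below the threshold; otherwise they are taken against all of
#' the region's other arrays.  Samples scoring below
#' `median(scores) - 3 * mad(scores)` (scaled MAD, as in [stats::mad()],
#' with median and MAD estimated over the whole region) are flagged and
#' removed.  Regions with fewer than four samples are skipped with a
#' warning.
#'
#' @param ds An [ExpressionDataset-class] (one or more regions).
#' @return list with `dataset` (outliers removed) and `report`, a list
#'   with `probes_in`, `probes_kept`, `outliers_removed` (data.frame
#'   `sample_id`, `region`, `score`, `threshold`).
#' @export
detectOutliers <- function(ds) {
    si <- sampleInfo(ds)
    pi <- probeInfo(ds)
    x <- exprsMat(ds)
    if ("species" %in% colnames(pi) && any(pi$species == "mouse"))
        x <- x[pi$species == "mouse", , drop = FALSE]
    flagged <- list()
    for (region in unique(si$region)) {
        cols <- which(si$region == region)
        if (length(cols) < 4) {
            warning("region ", region, " has fewer than 4 samples; ",
                    "outlier detection skipped")
            next
        }
        cc <- stats::cor(x[, cols, drop = FALSE], method = "spearman")
        diag(cc) <- NA
        cell <- paste(si$time_h[cols], si$condition[cols])
        scores <- vapply(seq_along(cols), function(i) {
            mates <- which(cell == cell[i] & seq_along(cols) != i)
            ref <- if (length(mates) >= 3) mates else seq_along(cols)[-i]
            stats::median(cc[i, ref])
        }, numeric(1))
        thr <- stats::median(scores) - 3 * stats::mad(scores)
        bad <- which(scores < thr)
        if (length(bad))
            flagged[[region]] <- data.frame(
                sample_id = colnames(ds)[cols[bad]], region = region,
                score = unname(scores[bad]), threshold = thr,
                stringsAsFactors = FALSE)
    }
    out <- if (length(flagged)) do.call(rbind, flagged) else
        data.frame(sample_id = character(0), region = character(0),
                   score = numeric(0), threshold = numeric(0))
    rownames(out) <- NULL
    keep <- !(colnames(ds) %in% out$sample_id)
    list(dataset = ds[, keep],
         report = list(probes_in = nrow(ds), probes_kept = nrow(ds),
                       outliers_removed = out,
                       filter_threshold = NA_real_,
                       filter_fraction = NA_real_))
}

#' Detection-above-background probe filter
#'
#' Retains probes that (i) carry the requested `species` and `maturity`
#' flags and (ii) have a detection p-value strictly below `pThresh` on at
#' least `frac` of the supplied arrays (the boundary fraction is
#' inclusive).  The caller is expected to pass one region's samples,
#' after outlier removal, since detection is assessed per region.  Probe
#' order is preserved.  An empty result raises a warning, not an error.
#'
#' @param ds An [ExpressionDataset-class].
#' @param pThresh detection p-value threshold (strict `<`); default 0.06.
#' @param frac required fraction of arrays (inclusive `>=`); default 0.80.
#' @param species,maturity required probe flags; set to `NULL` to skip
#'   the corresponding check (e.g. for mRNA platforms).
#' @return The filtered [ExpressionDataset-class].
#' @export
detectionFilter <- function(ds, pThresh = 0.06, frac = 0.80,
                            species = "mouse", maturity = "mature") {
    pi <- probeInfo(ds)
    ok <- rep(TRUE, nrow(ds))
    if (!is.null(species) && "species" %in% colnames(pi))
        ok <- ok & pi$species == species
    if (!is.null(maturity) && "maturity" %in% colnames(pi))
        ok <- ok & pi$maturity == maturity
    detected <- rowMeans(detectionP(ds) < pThresh) >= frac
    keep <- ok & detected
    if (!any(keep))
        warning("detection filter removed every probe")
    ds[keep, ]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's value distribution to the across-sample mean of
#' sorted value vectors while preserving within-sample ranks; ties
#' receive the mean of the tied target quantiles.  Detection p-values
#' are carried through unchanged.
#'
#' @param ds An [ExpressionDataset-class] with at least two samples.
#' @return The normalized [ExpressionDataset-class].
#' @export
quantileNormalize <- function(ds) {
    if (ncol(ds) < 2)
        stop("quantile normalization needs at least two samples")
    x <- limma::normalizeQuantiles(exprsMat(ds), ties = TRUE)
    ExpressionDataset(x, detectionP(ds), sampleInfo(ds), probeInfo(ds))
}

#' One-call preprocessing for a single region
#'
#' Outlier removal first (scored on all mouse probes), then the
#' detection filter on the remaining arrays, then quantile
#' normalization -- the order used throughout the package.
#'
#' @inheritParams detectionFilter
#' @return list with `dataset` and the outlier `report` augmented with
#'   probe counts and the filter settings.
#' @export
preprocessRegion <- function(ds, pThresh = 0.06, frac = 0.80,
                             species = "mouse", maturity = "mature") {
    o <- detectOutliers(ds)
    filtered <- detectionFilter(o$dataset, pThresh = pThresh, frac = frac,
                                species = species, maturity = maturity)
    rep <- o$report
    rep$probes_in <- nrow(ds)
    rep$probes_kept <- nrow(filtered)
    rep$filter_threshold <- pThresh
    rep$filter_fraction <- frac
    list(dataset = quantileNormalize(filtered), report = rep)
}
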