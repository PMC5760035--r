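#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

#' Container for a probe-by-sample expression study
#'
#' `ExpressionDataset` extends [SummarizedExperiment::SummarizedExperiment]
#' with two mandatory assays: `"exprs"` (log2 intensities) and
#' `"detectionP"` (per-probe, per-sample detection p-values, the probability
#' that the observed signal arises from background).  Column data carry the
#' sample annotation (`region`, `time_h`, `condition`, `animal_id`); row
#' data carry the probe annotation (`species`, `maturity`, `annotation`).
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- NULL
    if (!all(c("exprs", "detectionP") %in% assayNames(object)))
        msg <- c(msg, "assays 'exprs' and 'detectionP' are required")
    else {
        dp <- assay(object, "detectionP")
        if (any(dp < 0 | dp > 1, na.rm = TRUE))
            msg <- c(msg, "detection p-values must lie in [0, 1]")
    }
    need <- c("region", "time_h", "condition", "animal_id")
    if (!all(need %in% colnames(colData(object))))
        msg <- c(msg, paste("colData must contain",
                            paste(need, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids are not allowed")
    if (is.null(msg)) TRUE else msg
})

#' Configuration of the synthetic two-group time-course generator
#'
#' Holds every knob of the synthetic study: design size, planted fold
#' changes (signed linear convention, magnitudes >= 1), the miRNA-to-target
#' lag model, measurement noise, outlier samples, decoy interactions and
#' the knowledgebase layout.  Identical configuration plus seed yields
#' bit-identical output.
#'
#' @slot seed integer RNG seed.
#' @slot nRegions number of brain regions (1-3; named AMY, NAC, PFC).
#' @slot timesH time points in hours after the last exposure.
#' @slot nPerGroup animals per condition per time point.
#' @slot nMirnaProbes,nMrnaProbes probes on each platform.
#' @slot nDeMirnaPerTime planted differentially expressed miRNAs per
#'   (region, time).
#' @slot nTargetsPerMirna planted targets per differentially expressed
#'   miRNA, distributed over the lag-model times.
#' @slot mirnaFcRange,mrnaFcRange magnitude range of planted signed linear
#'   fold changes.
#' @slot lagModel named list mapping miRNA change time (as character) to
#'   target change times; every target time is at or after the miRNA time.
#' @slot sameSignFraction fraction of planted targets regulated in the same
#'   direction as their miRNA (default 0: opposite-sign repression).
#' @slot sharedTargetFraction fraction of each 8h miRNA's 120h targets
#'   drawn from the 120h targets of 0h miRNAs, planting genes regulated
#'   from both time points (the ground-truth critical genes).
#' @slot noiseSd residual standard deviation in log2 units.
#' @slot nOutlierSamples samples receiving a global +3*noiseSd shift plus
#'   per-probe disturbance of the same scale.
#' @slot decoyInteractionFraction decoy interaction records added as a
#'   fraction of the true-pair count.
#' @slot kbNMolecules,kbMeanDegree,kbNPlantedHubs knowledgebase size, mean
#'   degree and number of planted high-degree hub molecules.
#' @export
setClass("SimulationConfig",
    representation(
        seed = "integer", nRegions = "integer", timesH = "integer",
        nPerGroup = "integer", nMirnaProbes = "integer",
        nMrnaProbes = "integer", nDeMirnaPerTime = "integer",
        nTargetsPerMirna = "integer",
        mirnaFcRange = "numeric", mrnaFcRange = "numeric",
        lagModel = "list", sameSignFraction = "numeric",
        sharedTargetFraction = "numeric", noiseSd = "numeric",
        nOutlierSamples = "integer", decoyInteractionFraction = "numeric",
        kbNMolecules = "integer", kbMeanDegree = "integer",
        kbNPlantedHubs = "integer"),
    prototype(
        seed = 1L, nRegions = 3L, timesH = c(0L, 8L, 120L),
        nPerGroup = 8L, nMirnaProbes = 600L, nMrnaProbes = 2400L,
        nDeMirnaPerTime = 15L, nTargetsPerMirna = 4L,
        mirnaFcRange = c(1.2, 1.6), mrnaFcRange = c(1.03, 1.11),
        lagModel = list(`0` = c(8, 120), `8` = 120, `120` = numeric(0)),
        sameSignFraction = 0, sharedTargetFraction = 0.5,
        noiseSd = 0.04, nOutlierSamples = 2L,
        decoyInteractionFraction = 0.5,
        kbNMolecules = 3500L, kbMeanDegree = 8L, kbNPlantedHubs = 2L))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@nRegions < 1L || object@nRegions > 3L)
        msg <- c(msg, "nRegions must be 1, 2 or 3")
    if (any(object@mirnaFcRange < 1) || any(object@mrnaFcRange < 1))
        msg <- c(msg, "fold-change magnitudes must be >= 1 (signed linear convention)")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be non-negative")
    for (tm in names(object@lagModel)) {
        tt <- object@lagModel[[tm]]
        if (length(tt) && any(tt < as.numeric(tm)))
            msg <- c(msg, "lagModel: every target time must be at or after the miRNA time")
    }
    if (object@decoyInteractionFraction < 0)
        msg <- c(msg, "decoyInteractionFraction must be >= 0")
    if (object@kbMeanDegree >= object@kbNMolecules)
        msg <- c(msg, "kbMeanDegree must be smaller than kbNMolecules")
    if (is.null(msg)) TRUE else msg
})

#' Ground truth of a synthetic study
#'
#' Records what the generator planted, so downstream stages can be scored:
#' differentially expressed miRNAs and targets (with region, time and
#' signed fold change), true miRNA-target pairs with their temporal lag,
#' ground-truth critical genes (targets regulated at 120h by both a 0h and
#' an 8h miRNA), planted knowledgebase hubs, planted outlier samples and
#' the cell-type list carrying planted enrichment.
#'
#' @export
setClass("GroundTruth",
    representation(
        deMirnas = "data.frame", deTargets = "data.frame",
        truePairs = "data.frame", criticalGenes = "data.frame",
        plantedHubs = "character", outlierSamples = "character",
        enrichedCellType = "character"),
    prototype(plantedHubs = character(0), outlierSamples = character(0),
              enrichedCellType = character(0)))

setValidity("GroundTruth", function(object) {
    tp <- object@truePairs
    if (nrow(tp) && any(tp$target_time_h < tp$mirna_time_h))
        return("true pairs must have target time at or after miRNA time")
    TRUE
})

#' Empirical-Bayes hyperparameters of the moderated t-statistic
#'
#' Prior degrees of freedom `d0` (possibly infinite) and prior variance
#' `s0Sq` of the scaled inverse-chi-squared prior on residual variances.
#'
#' @export
setClass("EBayesHyper", representation(d0 = "numeric", s0Sq = "numeric"))

setValidity("EBayesHyper", function(object) {
    msg <- NULL
    if (length(object@d0) != 1L || object@d0 < 0)
        msg <- c(msg, "d0 must be a single value >= 0")
    if (length(object@s0Sq) != 1L || object@s0Sq <= 0)
        msg <- c(msg, "s0Sq must be a single positive value")
    if (is.null(msg)) TRUE else msg
})

#' One temporally paired miRNA/target dataset
#'
#' Pairs miRNAs differentially expressed at `mirnaTimeH` with their
#' confidence-passing targets differentially expressed at `targetTimeH`
#' (at or after the miRNA time) in one brain region.  Named
#' `"XhDEmiR/YhDEtargets"`; six such datasets exist per region.
#'
#' @export
setClass("PairedDataset",
    representation(region = "character", mirnaTimeH = "numeric",
                   targetTimeH = "numeric", name = "character",
                   mirnas = "character", targets = "character",
                   pairs = "data.frame"))

setValidity("PairedDataset", function(object) {
    msg <- NULL
    if (object@targetTimeH < object@mirnaTimeH)
        msg <- c(msg, "target time must be at or after miRNA time")
    p <- object@pairs
    if (nrow(p)) {
        if (!all(p$mirna %in% object@mirnas) ||
            !all(p$gene %in% object@targets))
            msg <- c(msg, "pairs must draw from the dataset's miRNA and target sets")
    }
    if (is.null(msg)) TRUE else msg
})

#' A molecule-interaction knowledgebase
#'
#' A simple undirected graph over molecules (genes, miRNAs and other
#' species) with a molecule attribute table (`molecule`, `type`,
#' `family`).  Backed by an [igraph::igraph] object in slot `graph`.
#'
#' @export
setClass("KnowledgebaseGraph",
    representation(graph = "ANY", molecules = "data.frame"))

#' A fixed-size molecule network grown on the knowledgebase
#'
#' A connected set of at most `sizeLimit` molecules seeded from the focus
#' molecules of one paired dataset, with its Fisher-exact enrichment score
#' (-log10 of the right-tail hypergeometric p-value for focus-molecule
#' content) and its rank among the dataset's networks.
#'
#' @export
setClass("Network",
    representation(molecules = "character", focus = "character",
                   edges = "data.frame", score = "numeric",
                   rank = "integer", sourceDataset = "character",
                   sizeLimit = "integer"),
    prototype(score = NA_real_, rank = NA_integer_, sizeLimit = 35L))

setValidity("Network", function(object) {
    msg <- NULL
    if (length(object@molecules) > object@sizeLimit)
        msg <- c(msg, "network exceeds its size limit")
    if (!all(object@focus %in% object@molecules))
        msg <- c(msg, "focus molecules must be network members")
    if (anyDuplicated(object@molecules))
        msg <- c(msg, "duplicate molecules in network")
    if (is.null(msg)) TRUE else msg
})

#' A clustering of temporal profiles with its validation measures
#'
#' Stores the winning algorithm and cluster count, the assignment of each
#' profile to a cluster (ids 1..k, all non-empty), the internal validation
#' measures (connectivity, Dunn index, mean silhouette width) and, when
#' produced by [selectSolution()], the full evaluation grid.
#'
#' @export
setClass("ClusterSolution",
    representation(algorithm = "character", k = "integer",
                   assignment = "integer", measures = "numeric",
                   grid = "data.frame"),
    prototype(grid = data.frame()))

setValidity("ClusterSolution", function(object) {
    msg <- NULL
    a <- object@assignment
    if (length(a) && !setequal(unique(a), seq_len(object@k)))
        msg <- c(msg, "cluster ids must be 1..k with no empty cluster")
    m <- object@measures
    if (!is.na(m["silhouette"]) &&
        (m["silhouette"] < -1 || m["silhouette"] > 1))
        msg <- c(msg, "silhouette must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ExpressionDataset", function(object) {
    cat("ExpressionDataset:", nrow(object), "probes x", ncol(object),
        "samples\n")
    cd <- colData(object)
    cat("  regions:", paste(sort(unique(cd$region)), collapse = ", "),
        "| times (h):", paste(sort(unique(cd$time_h)), collapse = ", "),
        "\n")
    callNextMethod()
})

setMethod("show", "PairedDataset", function(object) {
    cat("PairedDataset", sQuote(object@name), "in", object@region, "-",
        length(object@mirnas), "miRNAs,", length(object@targets),
        "targets,", nrow(object@pairs), "pairs\n")
})

setMethod("show", "Network", function(object) {
    cat("Network (rank", object@rank, ") from", object@sourceDataset,
        ":", length(object@molecules), "molecules,",
        length(object@focus), "focus, score",
        format(object@score, digits = 4), "\n")
})

setMethod("show", "ClusterSolution", function(object) {
    cat("ClusterSolution:", object@algorithm, "with k =", object@k, "\n")
    print(round(object@measures, 4))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: seed", object@seed, "|", object@nRegions,
        "regions x", length(object@timesH), "times x 2 x",
        object@nPerGroup, "animals |", object@nMirnaProbes,
        "miRNA probes,", object@nMrnaProbes, "mRNA probes\n")
})
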