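#' Confidence-filter miRNA-target interaction records
#'
#' Keeps experimentally observed interactions unconditionally, and
#' predicted interactions only when predicted with high confidence for a
#' conserved miRNA that has at least one conserved site on the target or
#' a total context score of -0.4 or less (boundary inclusive).
#'
#' @param records data.frame with columns `mirna_id`, `gene_id`,
#'   `evidence` (`experimental`/`predicted_high`/`predicted_low`),
#'   `mirna_conserved`, `n_conserved_sites`, `context_score`.
#' @return The confidence-passing subset, same columns.
#' @export
confidenceFilter <- function(records) {
    stopifnot(all(c("evidence", "mirna_conserved", "n_conserved_sites",
                    "context_score") %in% colnames(records)))
    keep <- records$evidence == "experimental" |
        (records$evidence == "predicted_high" &
         records$mirna_conserved &
         (records$n_conserved_sites >= 1 | records$context_score <= -0.4))
    records[keep, , drop = FALSE]
}

#' Temporal pairing of DE miRNAs with DE targets
#'
#' Builds the six paired datasets of one region: for every time
#' combination with the target at or after the miRNA --
#' (0,0), (0,8), (0,120), (8,8), (8,120), (120,120) h -- the dataset
#' holds all (miRNA, gene) pairs where the miRNA is DE at the miRNA time,
#' the gene is DE at the target time, and a confidence-passing
#' interaction record links them.  Changes in a miRNA may only precede
#' (or accompany) changes in its target, never follow them.  Empty
#' datasets are still emitted under their name
#' (`"XhDEmiR/YhDEtargets"`).
#'
#' @param deMirnas named list of DE miRNA identifier vectors, one per
#'   time point (names `"0"`, `"8"`, `"120"`).
#' @param deTargets named list of DE gene identifier vectors, same names.
#' @param records confidence-filtered interaction records (see
#'   [confidenceFilter()]; filtering is the caller's responsibility).
#' @param region region label stored in each dataset.
#' @param times the ordered time grid; defaults to `c(0, 8, 120)`.
#' @return named list of [PairedDataset-class] objects, one per valid
#'   (miRNA time, target time) combination.
#' @export
temporalPairing <- function(deMirnas, deTargets, records, region = "NA",
                            times = c(0, 8, 120)) {
    out <- list()
    key <- paste(records$mirna_id, records$gene_id)
    for (tm in times) for (tt in times[times >= tm]) {
        m <- deMirnas[[as.character(tm)]]
        g <- deTargets[[as.character(tt)]]
        sel <- records$mirna_id %in% m & records$gene_id %in% g
        pr <- unique(data.frame(mirna = records$mirna_id[sel],
                                gene = records$gene_id[sel],
                                evidence = records$evidence[sel],
                                stringsAsFactors = FALSE))
        nm <- sprintf("%dhDEmiR/%dhDEtargets", tm, tt)
        out[[nm]] <- new("PairedDataset", region = region,
                         mirnaTimeH = tm, targetTimeH = tt, name = nm,
                         mirnas = sort(unique(pr$mirna)),
                         targets = sort(unique(pr$gene)),
                         pairs = pr[order(pr$mirna, pr$gene), ,
                                    drop = FALSE])
    }
    out
}

#' Shared-target proportion between two time points
#'
#' The number of targets shared between the earlier and the later time
#' point divided by the total number of targets at the earlier time
#' point, times 100.  Undefined (returned as `NA`) when the earlier set
#' is empty.
#'
#' @param earlier,later character vectors of target identifiers, with
#'   `earlier` from the earlier time point.
#' @return percentage in `[0, 100]`, or `NA` for an empty earlier set.
#' @export
overlapProportion <- function(earlier, later) {
    earlier <- unique(earlier)
    if (!length(earlier)) return(NA_real_)
    100 * length(intersect(earlier, unique(later))) / length(earlier)
}

#' Targets of 0h miRNAs dysregulated at multiple time points
#'
#' Partitions the targets of 0h-DE miRNAs by the exact pattern of time
#' points at which they are themselves DE: those DE at all of 0, 8 and
#' 120 h, and those DE at 0 and 120 h but not 8 h.
#'
#' @param targetsByTime named list (`"0"`, `"8"`, `"120"`) of the DE
#'   status sets, restricted to targets of 0h-DE miRNAs.
#' @return list with elements `all_three` and `t0_t120_only`.
#' @export
multiTimeTargets <- function(targetsByTime) {
    t0 <- targetsByTime[["0"]]; t8 <- targetsByTime[["8"]]
    t120 <- targetsByTime[["120"]]
    list(all_three = sort(Reduce(intersect, list(t0, t8, t120))),
         t0_t120_only = sort(setdiff(intersect(t0, t120), t8)))
}

#' Three-set region overlap summary
#'
#' Assigns every identifier in the union of the per-region sets to one of
#' the seven intersection classes of a three-set Venn partition and
#' counts each class.  Class counts always sum to the union size.
#'
#' @param sets named list of up to three character vectors (one per
#'   region).
#' @return named integer vector; names like `"AMY"`, `"AMY&NAC"`,
#'   `"AMY&NAC&PFC"` built from the input names.
#' @export
regionOverlapSummary <- function(sets) {
    stopifnot(length(sets) >= 2, !is.null(names(sets)))
    ids <- unique(unlist(sets))
    member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
    if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
    cls <- apply(member, 1, function(row)
        paste(names(sets)[row], collapse = "&"))
    ## enumerate all non-empty subsets so absent classes report 0
    n <- length(sets)
    labels <- unlist(lapply(seq_len(n), function(k)
        utils::combn(names(sets), k, paste, collapse = "&")))
    counts <- stats::setNames(integer(length(labels)), labels)
    tab <- table(cls)
    counts[names(tab)] <- as.integer(tab)
    counts
}
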