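#' Create a simulation configuration
#'
#' Builds a [SimulationConfig-class] with the package defaults: a
#' three-region, three-time-point (0, 8, 120 h) two-group design with 8
#' treated and 8 control animals per time point (144 samples per platform
#' across regions), small signed linear fold changes, an opposite-sign
#' miRNA-to-target lag model (miRNA change at 0 h drives target changes at
#' 8 and 120 h; change at 8 h drives targets at 120 h), decoy interaction
#' records, and a heavy-tailed knowledgebase with planted hub molecules.
#'
#' @param seed integer RNG seed; the sole source of randomness.
#' @param ... any [SimulationConfig-class] slot to override, e.g.
#'   `noiseSd = 0.25` or `nDeMirnaPerTime = 0` for a null study.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, nRegions = 1L, nMrnaProbes = 200L)
#' @export
simulationConfig <- function(seed = 1L, ...) {
    cfg <- new("SimulationConfig")
    args <- c(list(seed = seed), list(...))
    intSlots <- c("seed", "nRegions", "timesH", "nPerGroup",
                  "nMirnaProbes", "nMrnaProbes", "nDeMirnaPerTime",
                  "nTargetsPerMirna", "nOutlierSamples", "kbNMolecules",
                  "kbMeanDegree", "kbNPlantedHubs")
    for (nm in names(args)) {
        if (!nm %in% slotNames(cfg))
            stop("unknown configuration field ", sQuote(nm))
        val <- args[[nm]]
        if (nm %in% intSlots) val <- as.integer(val)
        slot(cfg, nm) <- val
    }
    validObject(cfg)
    cfg
}

regionNames <- function(config) c("AMY", "NAC", "PFC")[seq_len(config@nRegions)]

geneUniverse <- function(config) {
    nDup <- round(0.05 * config@nMrnaProbes)
    sprintf("Gene%04d", seq_len(config@nMrnaProbes - nDup))
}

mirnaUniverse <- function(config) sprintf("miR-%04d", seq_len(config@nMirnaProbes))

## Sample table for one platform: every region x time x condition x animal.
buildSampleTable <- function(config) {
    out <- list()
    for (region in regionNames(config)) {
        for (tm in config@timesH) {
            cond <- rep(c("treated", "control"), each = config@nPerGroup)
            idx <- seq_len(2L * config@nPerGroup)
            out[[length(out) + 1L]] <- data.frame(
                sample_id = sprintf("%s_%dh_%s_%02d", region, tm,
                                    ifelse(cond == "treated", "trt", "ctl"),
                                    idx),
                region = region, time_h = tm, condition = cond,
                animal_id = sprintf("t%d_a%02d", tm, idx),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Simulate paired miRNA and mRNA expression studies
#'
#' Generates two [ExpressionDataset-class] objects (miRNA and mRNA
#' platforms) over the same animals, plus the [GroundTruth-class] of what
#' was planted.  Log2 intensities follow
#' `Normal(mu_probe, noiseSd)` with probe baselines drawn from
#' `Normal(7, 1.5)` for expressed probes and `Normal(4.2, 0.8)` for
#' background-level probes; detection p-values are the upper-tail
#' probability of each intensity under the background distribution
#' `Normal(4, 1)`.  Planted miRNAs are shifted in the treated group by
#' `log2(|FC|)` with the drawn sign at their change time; their planted
#' targets are shifted (by default in the opposite direction) at the
#' lag-model times.  Outlier samples receive a global `+3 * noiseSd` shift
#' plus an independent per-probe disturbance of the same scale.
#'
#' @param config A [SimulationConfig-class].
#' @return list with elements `mirna`, `mrna` ([ExpressionDataset-class])
#'   and `truth` ([GroundTruth-class]).
#' @export
simulateExpression <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed)
    regions <- regionNames(config)
    times <- config@timesH
    samples <- buildSampleTable(config)

    ## ---- miRNA platform probe annotation --------------------------------
    nMir <- config@nMirnaProbes
    mirAnnot <- mirnaUniverse(config)
    mirSpecies <- ifelse(stats::runif(nMir) < 0.8, "mouse", "other")
    mirMaturity <- ifelse(stats::runif(nMir) < 0.95, "mature", "precursor")
    eligible <- mirSpecies == "mouse" & mirMaturity == "mature"
    mirExpressed <- ifelse(eligible, stats::runif(nMir) < 0.9,
                           stats::runif(nMir) < 0.5)
    mirProbes <- data.frame(
        probe_id = sprintf("miRp%04d", seq_len(nMir)),
        species = mirSpecies, maturity = mirMaturity,
        annotation = mirAnnot, stringsAsFactors = FALSE)

    ## ---- mRNA platform probe annotation (5% duplicate probes) -----------
    genes <- geneUniverse(config)
    nDup <- config@nMrnaProbes - length(genes)
    dupGenes <- if (nDup > 0) sample(genes, nDup) else character(0)
    mrnaAnnot <- c(genes, dupGenes)
    geneExpressed <- stats::setNames(stats::runif(length(genes)) < 0.9, genes)
    mrnaProbes <- data.frame(
        probe_id = sprintf("mRp%05d", seq_along(mrnaAnnot)),
        species = "mouse", maturity = "mature",
        annotation = mrnaAnnot, stringsAsFactors = FALSE)

    ## ---- plant DE miRNAs and their lagged targets -----------------------
    deMir <- list(); deTar <- list(); pairs <- list()
    pool <- which(eligible & mirExpressed)
    need <- config@nDeMirnaPerTime * length(times)
    if (config@nDeMirnaPerTime > 0 && need > length(pool))
        stop("configuration error: nDeMirnaPerTime exceeds the eligible probe pool")
    exprGenes <- genes[geneExpressed[genes]]
    drawFc <- function(n, rng) {
        mag <- stats::runif(n, rng[1], rng[2])
        sgn <- sample(c(-1, 1), n, replace = TRUE)
        sgn * mag
    }
    for (region in regions) {
        if (config@nDeMirnaPerTime == 0) next
        picks <- sample(pool, need)
        tarPool120 <- character(0)  # 120h targets of this region's 0h miRNAs
        for (ti in seq_along(times)) {
            tm <- times[ti]
            sel <- picks[seq.int((ti - 1L) * config@nDeMirnaPerTime + 1L,
                                 ti * config@nDeMirnaPerTime)]
            fc <- drawFc(length(sel), config@mirnaFcRange)
            deMir[[length(deMir) + 1L]] <- data.frame(
                probe = mirProbes$probe_id[sel],
                annotation = mirAnnot[sel], region = region,
                time_h = tm, fc = fc, stringsAsFactors = FALSE)
            lagTimes <- config@lagModel[[as.character(tm)]]
            if (is.null(lagTimes) || !length(lagTimes)) next
            for (j in seq_along(sel)) {
                nT <- config@nTargetsPerMirna
                if (nT == 0) next
                ## 8h miRNAs reuse part of the 0h miRNAs' 120h target pool
                ## so some genes are regulated from both time points.
                nShared <- if (tm == 8 && length(tarPool120))
                    min(round(config@sharedTargetFraction * nT),
                        length(tarPool120)) else 0L
                tg <- character(0)
                if (nShared > 0)
                    tg <- sample(tarPool120, nShared)
                tg <- c(tg, sample(setdiff(exprGenes, tg), nT - length(tg)))
                tt <- sample(rep(lagTimes, length.out = nT))
                sgn <- ifelse(stats::runif(nT) < config@sameSignFraction,
                              sign(fc[j]), -sign(fc[j]))
                mag <- stats::runif(nT, config@mrnaFcRange[1],
                                    config@mrnaFcRange[2])
                deTar[[length(deTar) + 1L]] <- data.frame(
                    gene = tg, region = region, time_h = tt,
                    fc = sgn * mag, stringsAsFactors = FALSE)
                pairs[[length(pairs) + 1L]] <- data.frame(
                    mirna = mirAnnot[sel[j]], gene = tg, region = region,
                    mirna_time_h = tm, target_time_h = tt,
                    stringsAsFactors = FALSE)
                if (tm == 0)
                    tarPool120 <- union(tarPool120, tg[tt == 120])
            }
        }
    }
    deMir <- if (length(deMir)) do.call(rbind, deMir) else
        data.frame(probe = character(0), annotation = character(0),
                   region = character(0), time_h = numeric(0), fc = numeric(0))
    deTar <- if (length(deTar)) do.call(rbind, deTar) else
        data.frame(gene = character(0), region = character(0),
                   time_h = numeric(0), fc = numeric(0))
    truePairs <- if (length(pairs)) do.call(rbind, pairs) else
        data.frame(mirna = character(0), gene = character(0),
                   region = character(0), mirna_time_h = numeric(0),
                   target_time_h = numeric(0))
    ## first planting of a (gene, region, time) wins; later ones only add pairs
    deTar <- deTar[!duplicated(deTar[c("gene", "region", "time_h")]), ,
                   drop = FALSE]
    truePairs <- unique(truePairs)

    ## ground-truth critical genes: 120h targets regulated by both a 0h and
    ## an 8h miRNA of the same region
    crit <- list()
    for (region in regions) {
        tp <- truePairs[truePairs$region == region &
                        truePairs$target_time_h == 120, , drop = FALSE]
        g <- intersect(tp$gene[tp$mirna_time_h == 0],
                       tp$gene[tp$mirna_time_h == 8])
        if (length(g))
            crit[[length(crit) + 1L]] <- data.frame(
                region = region, gene = sort(g), stringsAsFactors = FALSE)
    }
    crit <- if (length(crit)) do.call(rbind, crit) else
        data.frame(region = character(0), gene = character(0))

    ## ---- intensity matrices ---------------------------------------------
    makeMatrix <- function(probes, expressed, de, annotLevel) {
        P <- nrow(probes); S <- nrow(samples)
        baseline <- ifelse(expressed, stats::rnorm(P, 7, 1.5),
                           stats::rnorm(P, 4.2, 0.8))
        x <- baseline + matrix(stats::rnorm(P * S, 0, config@noiseSd), P, S)
        dimnames(x) <- list(probes$probe_id, samples$sample_id)
        if (nrow(de)) for (i in seq_len(nrow(de))) {
            rows <- if (annotLevel) which(probes$annotation == de[[1]][i])
                    else which(probes$probe_id == de[[1]][i])
            cols <- which(samples$region == de$region[i] &
                          samples$time_h == de$time_h[i] &
                          samples$condition == "treated")
            x[rows, cols] <- x[rows, cols] + log2(abs(de$fc[i])) * sign(de$fc[i])
        }
        x
    }
    xMir <- makeMatrix(mirProbes, mirExpressed, deMir, annotLevel = FALSE)
    xMrna <- makeMatrix(mrnaProbes, geneExpressed[mrnaAnnot], deTar,
                        annotLevel = TRUE)

    ## ---- outlier samples -------------------------------------------------
    outliers <- character(0)
    if (config@nOutlierSamples > 0) {
        outliers <- sort(sample(samples$sample_id, config@nOutlierSamples))
        shift <- 3 * config@noiseSd
        for (sid in outliers) {
            xMir[, sid] <- xMir[, sid] + shift +
                stats::rnorm(nrow(xMir), 0, shift)
            xMrna[, sid] <- xMrna[, sid] + shift +
                stats::rnorm(nrow(xMrna), 0, shift)
        }
    }

    detP <- function(x) stats::pnorm(x, mean = 4, sd = 1, lower.tail = FALSE)
    truth <- new("GroundTruth", deMirnas = deMir, deTargets = deTar,
                 truePairs = truePairs, criticalGenes = crit,
                 outlierSamples = outliers)
    list(mirna = ExpressionDataset(xMir, detP(xMir), samples, mirProbes),
         mrna = ExpressionDataset(xMrna, detP(xMrna), samples, mrnaProbes),
         truth = truth)
}

#' Simulate a miRNA-target interaction table
#'
#' Every true planted pair receives an interaction record that passes the
#' confidence filter (experimentally observed, or predicted with high
#' confidence via a conserved miRNA and a conserved site or a context
#' score of -0.4 or less).  Decoy records are added at
#' `decoyInteractionFraction` of the true-pair count; half of the decoys
#' deliberately fail the confidence filter (low-confidence prediction,
#' non-conserved miRNA, or context score above -0.4 with no conserved
#' site), the other half pass it but connect molecules that were not
#' planted as a regulating pair.
#'
#' @param config A [SimulationConfig-class].
#' @param truth The [GroundTruth-class] from [simulateExpression()].
#' @return data.frame with columns `mirna_id`, `gene_id`, `evidence`
#'   (`experimental` / `predicted_high` / `predicted_low`),
#'   `mirna_conserved`, `n_conserved_sites`, `context_score`.
#' @export
simulateInteractions <- function(config, truth) {
    stopifnot(is(truth, "GroundTruth"))
    set.seed(config@seed + 1L)
    tp <- unique(truth@truePairs[c("mirna", "gene")])
    makeTrue <- function(n) {
        kind <- sample(c("exp", "site", "score"), n, replace = TRUE)
        data.frame(
            mirna_id = tp$mirna, gene_id = tp$gene,
            evidence = ifelse(kind == "exp", "experimental", "predicted_high"),
            mirna_conserved = TRUE,
            n_conserved_sites = ifelse(kind == "site",
                                       sample(1:3, n, replace = TRUE), 0L),
            context_score = ifelse(kind == "score",
                                   stats::runif(n, -1, -0.4),
                                   round(stats::runif(n, -0.35, 0), 3)),
            stringsAsFactors = FALSE)
    }
    recs <- if (nrow(tp)) makeTrue(nrow(tp)) else
        data.frame(mirna_id = character(0), gene_id = character(0),
                   evidence = character(0), mirna_conserved = logical(0),
                   n_conserved_sites = integer(0), context_score = numeric(0))
    nDecoy <- round(config@decoyInteractionFraction * nrow(tp))
    if (nDecoy > 0) {
        mir <- mirnaUniverse(config); gen <- geneUniverse(config)
        seen <- paste(tp$mirna, tp$gene)
        dm <- character(0); dg <- character(0)
        while (length(dm) < nDecoy) {
            m <- sample(mir, nDecoy); g <- sample(gen, nDecoy)
            ok <- !(paste(m, g) %in% c(seen, paste(dm, dg)))
            dm <- c(dm, m[ok]); dg <- c(dg, g[ok])
        }
        dm <- dm[seq_len(nDecoy)]; dg <- dg[seq_len(nDecoy)]
        fail <- seq_len(nDecoy) <= ceiling(nDecoy / 2)
        mode <- sample(c("low", "noncons", "weak"), nDecoy, replace = TRUE)
        decoys <- data.frame(
            mirna_id = dm, gene_id = dg,
            evidence = ifelse(fail & mode == "low", "predicted_low",
                              "predicted_high"),
            mirna_conserved = !(fail & mode == "noncons"),
            n_conserved_sites = ifelse(fail, 0L,
                                       sample(1:2, nDecoy, replace = TRUE)),
            context_score = ifelse(fail, round(stats::runif(nDecoy, -0.39, -0.1), 3),
                                   round(stats::runif(nDecoy, -1, -0.5), 3)),
            stringsAsFactors = FALSE)
        ## passing decoys keep conserved sites; failing ones have none and a
        ## weak context score (or a low-confidence / non-conserved call)
        recs <- rbind(recs, decoys)
    }
    rownames(recs) <- NULL
    recs
}

#' Simulate an interaction knowledgebase, gene families and cell-type lists
#'
#' Builds a simple undirected molecule graph over all simulated genes and
#' miRNAs plus filler molecules, with a heavy-tailed (preferential
#' attachment) degree sequence.  Each planted hub is a filler molecule
#' wired to every molecule of the planted 0h- and 8h-derived paired
#' datasets (well over 20 dataset molecules) in every region, so the hubs
#' sit at the center of both temporal neighborhoods and hub
#' identification has a crisp truth.  Also emits gene
#' families (for network-merge expansion) and named cell-type gene lists,
#' one of which (`neuron`) is planted to be enriched for the study's
#' differentially expressed targets.
#'
#' @param config A [SimulationConfig-class].
#' @param truth The [GroundTruth-class] from [simulateExpression()].
#' @return list with elements `kb` ([KnowledgebaseGraph-class]),
#'   `cellTypeLists` (named list of gene vectors), `familyMap`
#'   (data.frame `molecule`, `family`) and `truth` (the input with
#'   `plantedHubs` and `enrichedCellType` filled in).
#' @export
simulateKnowledgebase <- function(config, truth) {
    stopifnot(is(truth, "GroundTruth"))
    set.seed(config@seed + 2L)
    genes <- geneUniverse(config)
    mirs <- mirnaUniverse(config)
    nCore <- length(genes) + length(mirs)
    if (config@kbNMolecules < nCore)
        stop("configuration error: kbNMolecules smaller than the number of simulated molecules")
    filler <- if (config@kbNMolecules > nCore)
        sprintf("KBmol%04d", seq_len(config@kbNMolecules - nCore)) else character(0)
    mols <- sample(c(genes, mirs, filler))  # random placement in the graph
    g <- igraph::sample_pa(config@kbNMolecules,
                           m = max(1L, round(config@kbMeanDegree / 2)),
                           directed = FALSE)
    igraph::V(g)$name <- mols

    ## planted hubs: wire to the planted paired-dataset molecules
    hubs <- character(0)
    if (config@kbNPlantedHubs > 0) {
        if (!length(filler))
            stop("planted hubs require filler molecules (increase kbNMolecules)")
        hubs <- sort(sample(filler, config@kbNPlantedHubs))
        tp <- truth@truePairs
        newEdges <- character(0)
        for (hub in hubs) {
            for (region in unique(tp$region)) {
                for (tm in c(0, 8)) {
                    sel <- tp[tp$region == region & tp$mirna_time_h == tm &
                              tp$target_time_h == 120, , drop = FALSE]
                    dsMols <- unique(c(sel$mirna, sel$gene))
                    newEdges <- c(newEdges, rbind(hub, dsMols))
                }
            }
        }
        if (length(newEdges))
            g <- igraph::add_edges(g, match(newEdges, igraph::V(g)$name))
    }
    g <- igraph::simplify(g)

    ## gene families (for merge expansion)
    famMap <- data.frame(molecule = character(0), family = character(0))
    famGenes <- sample(genes, min(90L, length(genes)))
    if (length(famGenes) >= 3) {
        nFam <- length(famGenes) %/% 3
        famMap <- data.frame(
            molecule = famGenes[seq_len(nFam * 3)],
            family = rep(sprintf("FAM%03d", seq_len(nFam)), each = 3),
            stringsAsFactors = FALSE)
    }
    molTable <- data.frame(
        molecule = igraph::V(g)$name,
        type = ifelse(igraph::V(g)$name %in% genes, "gene",
                      ifelse(igraph::V(g)$name %in% mirs, "mirna", "other")),
        family = famMap$family[match(igraph::V(g)$name, famMap$molecule)],
        stringsAsFactors = FALSE)
    kb <- new("KnowledgebaseGraph", graph = g, molecules = molTable)

    ## cell-type lists; 'neuron' planted enriched for DE targets
    deGenes <- unique(truth@deTargets$gene)
    lists <- list()
    for (nm in c("astrocyte", "microglia", "oligodendrocyte", "immune"))
        lists[[nm]] <- sort(sample(genes, min(80L, length(genes))))
    nPlant <- min(40L, length(deGenes))
    lists[["neuron"]] <- sort(unique(c(
        if (nPlant) sample(deGenes, nPlant) else character(0),
        sample(genes, 40L))))
    truth@enrichedCellType <- "neuron"
    truth@plantedHubs <- hubs
    list(kb = kb, cellTypeLists = lists, familyMap = famMap, truth = truth)
}

#' Simulate a complete study
#'
#' Convenience wrapper running [simulateExpression()],
#' [simulateInteractions()] and [simulateKnowledgebase()] from one
#' configuration.
#'
#' @param config A [SimulationConfig-class].
#' @return list with `mirna`, `mrna`, `truth`, `interactions`, `kb`,
#'   `cellTypeLists`, `familyMap`.
#' @export
simulateStudy <- function(config) {
    ex <- simulateExpression(config)
    interactions <- simulateInteractions(config, ex$truth)
    kbOut <- simulateKnowledgebase(config, ex$truth)
    list(mirna = ex$mirna, mrna = ex$mrna, truth = kbOut$truth,
         interactions = interactions, kb = kbOut$kb,
         cellTypeLists = kbOut$cellTypeLists, familyMap = kbOut$familyMap)
}

#' Simulate temporal profile patterns for clustering
#'
#' Generates `k` well-separated temporal shapes in the centered/scaled
#' profile space (scaled three-point profiles lie on a circle of radius
#' `sqrt(2)` in the zero-mean plane; patterns are placed at equal angles)
#' and `perPattern` noisy profiles per shape.
#'
#' @param k number of planted patterns.
#' @param perPattern profiles per pattern.
#' @param noiseSd standard deviation of the per-coordinate noise added to
#'   the raw (unscaled) profiles.
#' @param seed integer RNG seed.
#' @return list with `profiles` (matrix with columns `0h`, `8h`, `120h`)
#'   and `assignment` (integer vector of true pattern labels).
#' @export
simulateProfilePatterns <- function(k, perPattern, noiseSd = 0.15, seed = 1L) {
    set.seed(seed)
    u <- c(1, 0, -1) / sqrt(2)
    v <- c(1, -2, 1) / sqrt(6)
    theta <- 2 * pi * (seq_len(k) - 1) / k + 0.3
    centers <- sqrt(2) * (cos(theta) %o% u + sin(theta) %o% v)
    lab <- rep(seq_len(k), each = perPattern)
    x <- centers[lab, , drop = FALSE] +
        matrix(stats::rnorm(length(lab) * 3, 0, noiseSd), ncol = 3)
    dimnames(x) <- list(sprintf("profile%03d", seq_along(lab)),
                        c("0h", "8h", "120h"))
    list(profiles = x, assignment = lab)
}

#' Write a simulated study to plain-text files
#'
#' Emits the expression TSV trios for both platforms, the interaction
#' table TSV, the knowledgebase edge-list TSV, the molecule table TSV, the
#' family map TSV, cell-type gene sets in GMT, the ground truth as JSON
#' and the configuration as JSON.
#'
#' @param sim output of [simulateStudy()].
#' @param config the [SimulationConfig-class] used.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
writeSimulation <- function(sim, config, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeExpressionDataset(sim$mirna, dir, "mirna")
    writeExpressionDataset(sim$mrna, dir, "mrna")
    utils::write.table(sim$interactions, file.path(dir, "interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    el <- igraph::as_data_frame(sim$kb@graph, what = "edges")
    utils::write.table(el, file.path(dir, "kb_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$kb@molecules, file.path(dir, "kb_molecules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$familyMap, file.path(dir, "family_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeGmt(sim$cellTypeLists, file.path(dir, "cell_types.gmt"))
    truth <- sim$truth
    jsonlite::write_json(list(
        de_mirnas = truth@deMirnas, de_targets = truth@deTargets,
        true_pairs = truth@truePairs, critical_genes = truth@criticalGenes,
        planted_hubs = truth@plantedHubs,
        outlier_samples = truth@outlierSamples,
        enriched_cell_type = truth@enrichedCellType),
        file.path(dir, "ground_truth.json"), digits = NA)
    cfg <- lapply(slotNames(config), function(s) slot(config, s))
    names(cfg) <- slotNames(config)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @return `readGmt` returns a named list of character vectors.
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                    vapply(parts, `[`, character(1), 1))
}
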