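#' Pipeline configuration
#'
#' Bundles every threshold of the analysis with its default: detection
#' p < 0.06 on >= 80% of arrays, miRNA DE at nominal p <= 0.05, mRNA DE
#' at FDR <= 0.05 for 0/8 h and nominal p <= 0.05 for 120 h, interaction
#' context score <= -0.4, 35-molecule networks, 3 networks per dataset,
#' grow steps of 10 molecules, top-3 within-network degree for hub
#' calls, and the cluster-count search range 2..8.  Every run writes the
#' resolved configuration next to its outputs.
#'
#' @param seed integer seed; the only source of randomness, from which
#'   the simulation seed is derived.
#' @param simulation a [SimulationConfig-class]; defaults to
#'   `simulationConfig(seed = seed)`.
#' @param detectionPThresh,detectionFrac detection-filter settings.
#' @param alpha DE threshold applied per the role/time rule.
#' @param networkSize,nNetworks,growN,topK network-stage settings.
#' @param clusterKRange candidate cluster counts.
#' @return list of class `miRtempoConfig`.
#' @export
pipelineConfig <- function(seed = 1L,
                           simulation = simulationConfig(seed = seed),
                           detectionPThresh = 0.06, detectionFrac = 0.80,
                           alpha = 0.05, networkSize = 35L,
                           nNetworks = 3L, growN = 10L, topK = 3L,
                           clusterKRange = 2:8) {
    structure(list(seed = as.integer(seed), simulation = simulation,
                   detectionPThresh = detectionPThresh,
                   detectionFrac = detectionFrac, alpha = alpha,
                   networkSize = as.integer(networkSize),
                   nNetworks = as.integer(nNetworks),
                   growN = as.integer(growN), topK = as.integer(topK),
                   clusterKRange = as.integer(clusterKRange)),
              class = "miRtempoConfig")
}

withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("stage ", sQuote(stage), " failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Read a study from the on-disk layout written by [writeSimulation()]
#'
#' @param dir directory holding the TSV/GMT files.
#' @return list with the same elements as [simulateStudy()] except
#'   `truth` (input data carry no ground truth).
#' @export
readStudy <- function(dir) {
    needed <- c("mirna_exprs.tsv", "mirna_detp.tsv", "mirna_samples.tsv",
                "mirna_probes.tsv", "mrna_exprs.tsv", "mrna_detp.tsv",
                "mrna_samples.tsv", "mrna_probes.tsv", "interactions.tsv",
                "kb_edges.tsv", "kb_molecules.tsv", "family_map.tsv",
                "cell_types.gmt")
    missing <- needed[!file.exists(file.path(dir, needed))]
    if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "))
    mols <- utils::read.delim(file.path(dir, "kb_molecules.tsv"))
    list(mirna = readExpressionDataset(dir, "mirna"),
         mrna = readExpressionDataset(dir, "mrna"),
         interactions = utils::read.delim(file.path(dir, "interactions.tsv")),
         kb = knowledgebaseGraph(
             utils::read.delim(file.path(dir, "kb_edges.tsv")), mols),
         cellTypeLists = readGmt(file.path(dir, "cell_types.gmt")),
         familyMap = utils::read.delim(file.path(dir, "family_map.tsv")))
}

## DE-miRNA temporal profile matrix (annotation level, one row per miRNA
## DE at any time, columns = time points, entries = log2 ratios).
deProfileMatrix <- function(calledMir, times) {
    ba <- calledMir$byAnnotation
    deAnn <- sort(unique(ba$annotation[ba$is_de]))
    if (!length(deAnn)) return(NULL)
    prof <- sapply(times, function(tm) {
        sub <- ba[ba$time_h == tm, ]
        sub$logFC[match(deAnn, sub$annotation)]
    })
    prof <- matrix(prof, nrow = length(deAnn),
                   dimnames = list(deAnn, paste0(times, "h")))
    prof
}

#' Run the full temporal integration pipeline
#'
#' Per region: preprocessing (outlier removal, detection filter,
#' quantile normalization) of both platforms, moderated-t differential
#' expression with the role/time threshold scheme, confidence filtering
#' and temporal pairing into the six paired datasets, hierarchical
#' clustering of DE-miRNA temporal profiles with validation-measure
#' model selection, and knowledgebase network construction for the
#' three x-h-miRNA / 120h-target datasets with scoring, growing,
#' merging, critical-gene and hub identification, and cell-type
#' enrichment.  Writes per-region TSV/JSON outputs, the resolved
#' configuration, and a manifest of per-stage counts.  Deterministic
#' given the seed: rerunning with one seed reproduces the manifest byte
#' for byte.
#'
#' @param config a `miRtempoConfig` from [pipelineConfig()].
#' @param outdir output directory (created; overwritten if reused).
#' @param inputDir optional directory in the [writeSimulation()] layout
#'   to analyze instead of simulating (the synthetic generator is the
#'   default input source).
#' @return (invisibly) list with `manifest`, per-region `results` and
#'   the output directory.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir,
                        inputDir = NULL) {
    stopifnot(inherits(config, "miRtempoConfig"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    study <- if (is.null(inputDir))
        withStage("simulate", simulateStudy(config$simulation))
    else withStage("read_input", readStudy(inputDir))

    cfgOut <- config
    cfgOut$simulation <- {
        s <- lapply(slotNames(config$simulation), function(x)
            slot(config$simulation, x))
        names(s) <- slotNames(config$simulation)
        s
    }
    jsonlite::write_json(cfgOut, file.path(outdir, "config_resolved.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)

    records <- withStage("confidence_filter",
                         confidenceFilter(study$interactions))
    kb <- withStage("network", injectInteractions(study$kb, records))
    regions <- sort(unique(sampleInfo(study$mirna)$region))
    times <- sort(unique(sampleInfo(study$mirna)$time_h))
    results <- list(); manifest <- list()
    for (region in regions) {
        rdir <- file.path(outdir, region)
        dir.create(rdir, showWarnings = FALSE)

        preMir <- withStage("preprocess", preprocessRegion(
            subsetRegion(study$mirna, region),
            pThresh = config$detectionPThresh, frac = config$detectionFrac,
            species = "mouse", maturity = "mature"))
        preMrna <- withStage("preprocess", preprocessRegion(
            subsetRegion(study$mrna, region),
            pThresh = config$detectionPThresh, frac = config$detectionFrac,
            species = NULL, maturity = NULL))

        deMir <- withStage("diffexpr", runDE(preMir$dataset, region))
        deMrna <- withStage("diffexpr", runDE(preMrna$dataset, region))
        calledMir <- callDE(deMir, "mirna", alpha = config$alpha)
        calledMrna <- callDE(deMrna, "mrna", alpha = config$alpha)
        setsMir <- deSets(calledMir)
        setsMrna <- deSets(calledMrna)
        utils::write.table(calledMir$table,
            file.path(rdir, "de_mirna.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(calledMrna$table,
            file.path(rdir, "de_mrna.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

        paired <- withStage("target_pairing", temporalPairing(
            setsMir, setsMrna, records, region = region, times = times))
        pairTab <- do.call(rbind, lapply(paired, function(pd)
            if (nrow(pd@pairs)) data.frame(dataset = pd@name, pd@pairs,
                                           stringsAsFactors = FALSE)))
        if (!is.null(pairTab))
            utils::write.table(pairTab,
                file.path(rdir, "paired_datasets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
        tar0 <- lapply(paste0("0hDEmiR/", times, "hDEtargets"),
                       function(nm) paired[[nm]]@targets)
        names(tar0) <- as.character(times)
        overlap08 <- overlapProportion(tar0[["0"]], tar0[["8"]])
        multi <- multiTimeTargets(tar0)

        ## clustering of DE miRNA temporal profiles
        prof <- deProfileMatrix(calledMir, times)
        sol <- NULL
        if (!is.null(prof) && nrow(prof) >= 4) {
            scaled <- suppressWarnings(scaleProfiles(prof))
            sol <- withStage("clustering",
                             selectSolution(scaled,
                                            kRange = config$clusterKRange))
            utils::write.table(data.frame(
                mirna = names(sol@assignment),
                cluster = unname(sol@assignment), prof,
                check.names = FALSE),
                file.path(rdir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
        }

        ## network stage on the three x-h-miRNA / 120h-target datasets
        lateNames <- paste0(times, "hDEmiR/120hDEtargets")
        nets <- list()
        for (nm in lateNames) {
            pd <- paired[[nm]]
            mols <- union(pd@mirnas, pd@targets)
            nets[[nm]] <- if (length(mols))
                withStage("network", suppressWarnings(buildNetworks(
                    mols, kb, size = config$networkSize,
                    nNetworks = config$nNetworks,
                    sourceDataset = paste(region, nm)))) else list()
        }
        crit <- list(critical = character(0))
        if (length(nets[[lateNames[1]]]) && length(nets[[lateNames[2]]])) {
            dsMols <- unique(c(
                unlist(lapply(paired[lateNames[1:2]], function(pd)
                    c(pd@mirnas, pd@targets)))))
            crit <- withStage("network", mergeAndCriticalGenes(
                nets[[lateNames[1]]], nets[[lateNames[2]]],
                de120Genes = setsMrna[["120"]],
                datasetMolecules = dsMols, familyMap = study$familyMap))
        }
        critTab <- merge(
            data.frame(gene = crit$critical, stringsAsFactors = FALSE),
            calledMrna$byAnnotation[calledMrna$byAnnotation$time_h == 120,
                                    c("annotation", "fc_signed", "p")],
            by.x = "gene", by.y = "annotation", all.x = TRUE)
        utils::write.table(critTab[order(critTab$gene), ],
            file.path(rdir, "critical_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

        allNets <- unlist(nets, recursive = FALSE, use.names = FALSE)
        hubs <- if (sum(lengths(nets) > 0) >= 2)
            withStage("network", findHubs(allNets, topK = config$topK))
        else data.frame(molecule = character(0), n_datasets = integer(0),
                        datasets = character(0), max_degree = integer(0))
        utils::write.table(hubs, file.path(rdir, "hubs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(lapply(allNets, function(n) list(
            dataset = n@sourceDataset, rank = n@rank,
            score = round(n@score, 6), molecules = n@molecules,
            focus = n@focus)),
            file.path(rdir, "networks.json"), auto_unbox = TRUE,
            digits = NA, pretty = TRUE)

        ## cell-type enrichment of the 120h-target datasets
        universe <- unique(probeInfo(study$mrna)$annotation)
        lateTargets <- unique(unlist(lapply(paired[lateNames],
                                            function(pd) pd@targets)))
        enr <- lapply(study$cellTypeLists, function(gs)
            withStage("enrichment",
                      geneSetEnrichment(lateTargets, gs, universe)))
        enrTab <- data.frame(
            cell_type = names(enr),
            odds_ratio = vapply(enr, function(e) e$odds_ratio, numeric(1)),
            p = vapply(enr, function(e) e$p, numeric(1)),
            stringsAsFactors = FALSE)
        utils::write.table(enrTab, file.path(rdir, "cell_type_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

        results[[region]] <- list(
            preMir = preMir, preMrna = preMrna,
            calledMir = calledMir, calledMrna = calledMrna,
            paired = paired, clusters = sol, networks = nets,
            critical = crit, hubs = hubs, enrichment = enrTab,
            overlap08 = overlap08, multiTimeTargets = multi)
        manifest[[region]] <- list(
            mirna_samples_kept = ncol(preMir$dataset),
            mrna_samples_kept = ncol(preMrna$dataset),
            mirna_outliers_removed =
                nrow(preMir$report$outliers_removed),
            mrna_outliers_removed =
                nrow(preMrna$report$outliers_removed),
            mirna_probes_detected = nrow(preMir$dataset),
            mrna_probes_detected = nrow(preMrna$dataset),
            de_mirnas_per_time = lapply(setsMir, length),
            de_mrnas_per_time = lapply(setsMrna, length),
            de_mirnas_union = length(unique(unlist(setsMir))),
            n_paired_datasets = length(paired),
            paired_dataset_sizes = lapply(paired, function(pd)
                nrow(pd@pairs)),
            target_overlap_0h_vs_8h_pct =
                if (is.na(overlap08)) NULL else round(overlap08, 4),
            clusters_selected = if (is.null(sol)) NULL else
                list(algorithm = sol@algorithm, k = sol@k),
            n_networks = sum(lengths(nets)),
            top_network_score = if (length(allNets))
                round(max(vapply(allNets, function(n) n@score,
                                 numeric(1))), 6) else NULL,
            n_critical_genes = length(crit$critical),
            n_hubs = nrow(hubs))
    }
    manifest <- list(seed = config$seed, regions = regions,
                     per_region = manifest)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(manifest = manifest, results = results,
                   outdir = outdir))
}

#' Summary count tables across regions
#'
#' @param results the `results` element returned by [runPipeline()].
#' @return list with `de_counts` (region x role x time DE counts),
#'   `target_counts` (pairs and targets per paired dataset) and
#'   `region_overlap` (membership classes of DE miRNA sets across
#'   regions, when more than one region is present).
#' @export
summarizeCounts <- function(results) {
    deRows <- list(); tarRows <- list(); mirSets <- list()
    for (region in names(results)) {
        r <- results[[region]]
        for (role in c("mirna", "mrna")) {
            called <- if (role == "mirna") r$calledMir else r$calledMrna
            sets <- deSets(called)
            for (tm in names(sets))
                deRows[[length(deRows) + 1L]] <- data.frame(
                    region = region, role = role, time_h = as.numeric(tm),
                    n_de = length(sets[[tm]]), stringsAsFactors = FALSE)
        }
        mirSets[[region]] <- unique(unlist(deSets(r$calledMir)))
        for (pd in r$paired)
            tarRows[[length(tarRows) + 1L]] <- data.frame(
                region = region, dataset = pd@name,
                n_mirnas = length(pd@mirnas),
                n_targets = length(pd@targets),
                n_pairs = nrow(pd@pairs), stringsAsFactors = FALSE)
    }
    list(de_counts = do.call(rbind, deRows),
         target_counts = do.call(rbind, tarRows),
         region_overlap = if (length(mirSets) >= 2)
             regionOverlapSummary(mirSets) else NULL)
}
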