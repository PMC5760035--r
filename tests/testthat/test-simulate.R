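test_that("default design yields 16 animals x 3 regions x 3 times = 144 samples", {
    cfg <- simulationConfig(seed = 1, nMirnaProbes = 40L, nMrnaProbes = 60L,
                            nDeMirnaPerTime = 0L, nOutlierSamples = 0L)
    sim <- simulateExpression(cfg)
    expect_equal(ncol(sim$mirna), 144)
    expect_equal(ncol(sim$mrna), 144)
    si <- sampleInfo(sim$mirna)
    expect_setequal(unique(si$region), c("AMY", "NAC", "PFC"))
    expect_setequal(unique(si$time_h), c(0, 8, 120))
    tab <- table(si$region, si$time_h, si$condition)
    expect_true(all(tab == 8))
})

test_that("simulation is bit-identical under a fixed seed and differs across seeds", {
    cfg <- smallConfig(seed = 11, nOutlierSamples = 1L)
    a <- simulateExpression(cfg)
    b <- simulateExpression(cfg)
    expect_identical(exprsMat(a$mirna), exprsMat(b$mirna))
    expect_identical(exprsMat(a$mrna), exprsMat(b$mrna))
    expect_identical(a$truth@truePairs, b$truth@truePairs)
    c <- simulateExpression(smallConfig(seed = 12, nOutlierSamples = 1L))
    expect_false(identical(exprsMat(a$mirna), exprsMat(c$mirna)))
})

test_that("null simulation (no noise, unit fold changes) has identical group means", {
    cfg <- smallConfig(seed = 2, noiseSd = 0, nOutlierSamples = 0L,
                       mirnaFcRange = c(1, 1), mrnaFcRange = c(1, 1))
    sim <- simulateExpression(cfg)
    si <- sampleInfo(sim$mirna)
    x <- exprsMat(sim$mirna)
    for (tm in c(0, 8, 120)) {
        trt <- rowMeans(x[, si$time_h == tm & si$condition == "treated"])
        ctl <- rowMeans(x[, si$time_h == tm & si$condition == "control"])
        expect_equal(trt, ctl)
    }
})

test_that("planted structure respects the temporal lag and config errors are caught", {
    sim <- simulateExpression(smallConfig(seed = 3))
    tp <- sim$truth@truePairs
    expect_gt(nrow(tp), 0)
    expect_true(all(tp$target_time_h >= tp$mirna_time_h))
    ## every true pair joins a planted DE miRNA to a planted DE target
    dm <- sim$truth@deMirnas; dt <- sim$truth@deTargets
    expect_true(all(paste(tp$mirna, tp$region, tp$mirna_time_h) %in%
                    paste(dm$annotation, dm$region, dm$time_h)))
    expect_true(all(paste(tp$gene, tp$region, tp$target_time_h) %in%
                    paste(dt$gene, dt$region, dt$time_h)))
    ## critical genes are regulated from both 0h and 8h
    cg <- sim$truth@criticalGenes
    expect_gt(nrow(cg), 0)
    for (i in seq_len(min(5, nrow(cg)))) {
        sub <- tp[tp$gene == cg$gene[i] & tp$region == cg$region[i] &
                  tp$target_time_h == 120, ]
        expect_setequal(intersect(c(0, 8), sub$mirna_time_h), c(0, 8))
    }
    expect_error(simulateExpression(smallConfig(seed = 3,
                                                nDeMirnaPerTime = 500L)),
                 "configuration error")
})

test_that("planted effects shift group means by the planted log fold change", {
    cfg <- smallConfig(seed = 4, noiseSd = 0)
    sim <- simulateExpression(cfg)
    si <- sampleInfo(sim$mirna)
    x <- exprsMat(sim$mirna)
    dm <- sim$truth@deMirnas
    for (i in seq_len(nrow(dm))) {
        trt <- si$time_h == dm$time_h[i] & si$condition == "treated"
        ctl <- si$time_h == dm$time_h[i] & si$condition == "control"
        beta <- mean(x[dm$probe[i], trt]) - mean(x[dm$probe[i], ctl])
        expect_equal(signedFoldChange(beta), dm$fc[i], tolerance = 1e-12)
    }
})

test_that("detection p-values are the background upper tail and flag expressed probes", {
    sim <- simulateExpression(smallConfig(seed = 5))
    x <- exprsMat(sim$mirna); dp <- detectionP(sim$mirna)
    expect_equal(dp, pnorm(x, 4, 1, lower.tail = FALSE))
    expect_true(all(dp >= 0 & dp <= 1))
})

test_that("interaction table covers true pairs and decoys as configured", {
    cfg <- smallConfig(seed = 6, decoyInteractionFraction = 0)
    sim <- simulateExpression(cfg)
    rec0 <- simulateInteractions(cfg, sim$truth)
    tp <- unique(sim$truth@truePairs[c("mirna", "gene")])
    expect_equal(nrow(rec0), nrow(tp))
    expect_setequal(paste(rec0$mirna_id, rec0$gene_id),
                    paste(tp$mirna, tp$gene))
    ## every true-pair record passes the confidence filter
    expect_equal(nrow(confidenceFilter(rec0)), nrow(rec0))

    cfg2 <- smallConfig(seed = 6, decoyInteractionFraction = 0.5)
    rec <- simulateInteractions(cfg2, sim$truth)
    expect_equal(nrow(rec), nrow(tp) + round(0.5 * nrow(tp)))
    ## some decoys deliberately fail the filter
    expect_lt(nrow(confidenceFilter(rec)), nrow(rec))
})

test_that("knowledgebase is a simple graph with the configured mean degree and wired hubs", {
    cfg <- simulationConfig(seed = 7, nRegions = 1L, nMirnaProbes = 150L,
                            nMrnaProbes = 500L, nDeMirnaPerTime = 6L,
                            noiseSd = 0.1, nOutlierSamples = 0L,
                            kbNMolecules = 2000L, kbMeanDegree = 8L)
    sim <- simulateExpression(cfg)
    out <- simulateKnowledgebase(cfg, sim$truth)
    g <- out$kb@graph
    expect_true(igraph::is_simple(g))
    meanDeg <- mean(igraph::degree(g))
    expect_lt(abs(meanDeg / 8 - 1), 0.2)
    ## planted hubs are wired to >= 20 dataset molecules
    truth <- out$truth
    expect_length(truth@plantedHubs, cfg@kbNPlantedHubs)
    dsMols <- unique(c(truth@truePairs$mirna, truth@truePairs$gene))
    for (hub in truth@plantedHubs) {
        nb <- igraph::V(g)$name[as.integer(
            igraph::neighbors(g, hub))]
        expect_gte(length(intersect(nb, dsMols)), 20)
    }
    ## the enriched cell-type list carries planted DE targets
    expect_identical(truth@enrichedCellType, "neuron")
    expect_gt(length(intersect(out$cellTypeLists$neuron,
                               unique(truth@deTargets$gene))), 0)
})

test_that("GMT and TSV round trips preserve the simulated study", {
    dir <- withr::local_tempdir()
    sets <- list(a = c("g1", "g2"), b = c("g3", "g4", "g5"))
    writeGmt(sets, file.path(dir, "x.gmt"))
    expect_identical(readGmt(file.path(dir, "x.gmt")), sets)

    cfg <- smallConfig(seed = 8)
    sim <- simulateStudy(cfg)
    writeSimulation(sim, cfg, dir)
    back <- readStudy(dir)
    expect_equal(exprsMat(back$mirna), exprsMat(sim$mirna),
                 tolerance = 1e-12)
    expect_equal(sampleInfo(back$mrna), sampleInfo(sim$mrna))
    expect_equal(nrow(back$interactions), nrow(sim$interactions))
    expect_equal(igraph::ecount(back$kb@graph),
                 igraph::ecount(sim$kb@graph))
})

test_that("profile-pattern generator plants k well-separated shapes", {
    sim <- simulateProfilePatterns(4, 6, noiseSd = 0, seed = 1)
    expect_equal(dim(sim$profiles), c(24, 3))
    scaled <- scaleProfiles(sim$profiles)
    ## identical shapes collapse to identical scaled profiles
    expect_equal(length(unique(round(scaled %*% c(1, 2, 4), 8))), 4)
})
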