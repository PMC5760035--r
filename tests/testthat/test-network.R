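starKb <- function() {
    edges <- data.frame(from = "center", to = sprintf("leaf%02d", 1:40))
    knowledgebaseGraph(edges)
}

randomKb <- function(seed, n = 120, p = 0.05) {
    set.seed(seed)
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("mol%03d", seq_len(n))
    new("KnowledgebaseGraph", graph = g,
        molecules = data.frame(molecule = igraph::V(g)$name,
                               type = "other", family = NA_character_))
}

test_that("greedy construction on a star graph keeps the focus leaves", {
    kb <- starKb()
    focus <- c("center", sprintf("leaf%02d", 1:10))
    nets <- buildNetworks(focus, kb, size = 15, nNetworks = 1,
                          sourceDataset = "toy")
    expect_true(all(focus %in% nets[[1]]@molecules))
    expect_lte(length(nets[[1]]@molecules), 15)
    expect_equal(nets[[1]]@rank, 1L)
    expect_gt(nets[[1]]@score, 0)
})

test_that("networks are connected, capped at size, and focus-disjoint", {
    for (s in 1:20) {
        kb <- randomKb(s)
        set.seed(1000 + s)
        focus <- sample(igraph::V(kb@graph)$name, 40)
        nets <- suppressWarnings(buildNetworks(focus, kb, size = 35,
                                               nNetworks = 3,
                                               sourceDataset = "rand"))
        focusSeen <- character(0)
        for (net in nets) {
            expect_lte(length(net@molecules), 35)
            sub <- igraph::induced_subgraph(kb@graph, net@molecules)
            expect_true(igraph::is_connected(sub))
            expect_setequal(net@focus, intersect(net@molecules, focus))
            expect_length(intersect(net@focus, focusSeen), 0)
            focusSeen <- c(focusSeen, net@focus)
        }
        ## ranks ordered by score
        scores <- vapply(nets, function(n) n@score, numeric(1))
        expect_equal(order(-scores), seq_along(nets))
    }
})

test_that("a dataset with no knowledgebase edges yields single-focus components", {
    edges <- data.frame(from = c("a", "b"), to = c("x", "y"))
    kb <- knowledgebaseGraph(edges)
    nets <- buildNetworks(c("a", "b"), kb, size = 35, nNetworks = 2,
                          sourceDataset = "sparse")
    for (net in nets) expect_lte(length(net@focus), 1)
    expect_warning(out <- buildNetworks(c("zz"), kb, sourceDataset = "x"),
                   "knowledgebase")
    expect_length(out, 0)
})

test_that("network score equals the exhaustive hypergeometric tail", {
    mkNet <- function(nMol, nFocus) new("Network",
        molecules = sprintf("m%02d", seq_len(nMol)),
        focus = sprintf("m%02d", seq_len(nFocus)),
        edges = data.frame(from = character(0), to = character(0)),
        sourceDataset = "t", sizeLimit = 35L)
    ## N=100, F=10, |net|=5, f=5: p = C(10,5)/C(100,5)
    expect_equal(networkScore(mkNet(5, 5), 10, 100),
                 -log10(choose(10, 5) / choose(100, 5)), tolerance = 1e-9)
    ## f = 0 -> p = 1, score 0
    expect_equal(networkScore(mkNet(5, 0), 10, 100), 0)
    ## strictly increasing in f
    sc <- vapply(1:5, function(f) networkScore(mkNet(5, f), 10, 100),
                 numeric(1))
    expect_true(all(diff(sc) > 0))
    expect_error(networkScore(mkNet(5, 2), 200, 100), "exceeds")
    ## random instances vs brute-force tail sums, N <= 60
    set.seed(14)
    for (r in 1:50) {
        N <- sample(10:60, 1)
        F <- sample(1:(N - 1), 1)
        k <- sample(1:min(N, 35), 1)
        f <- sample(0:min(k, F), 1)
        net <- new("Network", molecules = sprintf("x%02d", seq_len(k)),
                   focus = sprintf("x%02d", seq_len(f)),
                   edges = data.frame(from = character(0),
                                      to = character(0)),
                   sourceDataset = "t", sizeLimit = 35L)
        expect_equal(10^(-networkScore(net, F, N)),
                     bruteHyperTail(f, F, N, k), tolerance = 1e-9)
    }
})

test_that("grow adds exactly the hand-ranked top candidates with edges", {
    ## network over m1..m4 (a path); 12 candidates with known edge counts
    net0 <- sprintf("m%d", 1:4)
    edges <- data.frame(from = c("m1", "m2", "m3"), to = c("m2", "m3", "m4"))
    cands <- sprintf("c%02d", 1:12)
    ## c01..c10 connect to 3,3,2,2,2,1,1,1,1,1 network members; c11, c12 none
    connect <- c(3, 3, 2, 2, 2, 1, 1, 1, 1, 1, 0, 0)
    for (i in seq_along(cands)) {
        if (connect[i] == 0) {
            edges <- rbind(edges, data.frame(from = cands[i], to = "iso"))
            next
        }
        edges <- rbind(edges, data.frame(from = cands[i],
                                         to = net0[seq_len(connect[i])]))
    }
    kb <- knowledgebaseGraph(edges)
    net <- new("Network", molecules = net0, focus = net0,
               edges = data.frame(from = c("m1", "m2", "m3"),
                                  to = c("m2", "m3", "m4")),
               sourceDataset = "t", sizeLimit = 35L)
    grown <- growNetwork(net, c(cands, "nonexistent"), kb, n = 10)
    expect_setequal(setdiff(grown@molecules, net0), cands[1:10])
    ## zero-edge candidates are never added, even under the cap
    grown2 <- growNetwork(net, cands[9:12], kb, n = 10)
    expect_setequal(setdiff(grown2@molecules, net0), cands[9:10])
    ## two sequential grows add at most 20 molecules
    g1 <- growNetwork(net, cands, kb, n = 10)
    g2 <- growNetwork(g1, sprintf("c%02d", 1:12), kb, n = 10)
    expect_lte(length(g2@molecules) - length(net0), 20)
})

test_that("merging expands gene families and intersects for critical genes", {
    mkNet <- function(mols, src) new("Network", molecules = mols,
        focus = mols, edges = data.frame(from = character(0),
                                         to = character(0)),
        sourceDataset = src, sizeLimit = 35L)
    fam <- data.frame(molecule = c("gA", "gA2", "gB"),
                      family = c("F1", "F1", "F2"))
    nets0 <- list(mkNet(c("gA", "gC"), "ds0"))
    nets8 <- list(mkNet(c("gA2", "gC", "gD"), "ds8"))
    out <- mergeAndCriticalGenes(nets0, nets8,
                                 de120Genes = c("gA", "gA2", "gC", "gZ"),
                                 datasetMolecules = c("gA", "gA2", "gC",
                                                      "gD"),
                                 familyMap = fam)
    ## gA2 joins merged_0h through family expansion; gC is shared directly
    expect_true("gA2" %in% out$merged_0h)
    expect_setequal(out$critical, c("gA", "gA2", "gC"))
    ## gD is in one merged network only -> not critical
    expect_false("gD" %in% out$critical)
})

test_that("hubs need top-degree membership in networks from two datasets", {
    mkNet <- function(edges, src) {
        mols <- unique(c(edges$from, edges$to))
        new("Network", molecules = mols, focus = character(0),
            edges = edges, sourceDataset = src, sizeLimit = 35L)
    }
    hubEdges <- data.frame(from = "hub", to = c("a", "b", "c", "d"))
    n1 <- mkNet(hubEdges, "ds0")
    n2 <- mkNet(hubEdges, "ds0")      # same dataset: must not qualify alone
    n3 <- mkNet(data.frame(from = "hub", to = c("e", "f", "g")), "ds8")
    sameDs <- findHubs(list(n1, n2), topK = 3)
    expect_false("hub" %in% sameDs$molecule)
    both <- findHubs(list(n1, n2, n3), topK = 3)
    expect_true("hub" %in% both$molecule)
    expect_equal(both$n_datasets[both$molecule == "hub"], 2L)
    ## networks from a single dataset only: no hubs, with a warning
    expect_warning(none <- findHubs(list(n1), topK = 3), "2 datasets")
    expect_equal(nrow(none), 0)
})

test_that("gene-set enrichment matches the hypergeometric tail and nulls are uniform", {
    universe <- sprintf("u%03d", 1:10)
    ## 2x2 table (4,1;1,4): dataset 5 genes, set 5 genes, overlap 4
    out <- geneSetEnrichment(universe[1:5], universe[c(1:4, 6)], universe)
    expect_equal(out$p, bruteHyperTail(4, 5, 10, 5), tolerance = 1e-12)
    ## perfect overlap of two half-universe sets is highly significant
    big <- sprintf("u%03d", 1:400)
    strong <- geneSetEnrichment(big[1:200], big[1:200], big)
    expect_lt(strong$p, 1e-10)
    expect_error(geneSetEnrichment("a", "a", character(0)), "universe")
    ## null simulation: p-values approximately uniform
    set.seed(15)
    uni <- sprintf("g%04d", 1:2000)
    gs <- sample(uni, 500)
    p <- replicate(200, geneSetEnrichment(sample(uni, 400), gs, uni)$p)
    expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("direction z-score counts sign consistency", {
    genes <- sprintf("g%d", 1:9)
    expected <- setNames(rep(1, 9), genes)
    expect_equal(directionZscore(expected[1:4], expected[1:4]), 2)
    obs <- setNames(c(1, 1, -1, -1), genes[1:4])
    expect_equal(directionZscore(expected[1:4], obs), 0)
    expect_equal(directionZscore(expected, -expected), -3)
    expect_true(is.na(directionZscore(setNames(0, "g1"),
                                      setNames(1, "g1"))))
})
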