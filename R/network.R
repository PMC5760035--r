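#' Construct a knowledgebase graph
#'
#' @param edges data.frame of undirected edges (`from`, `to`); self
#'   loops and duplicate edges are removed.
#' @param molecules optional data.frame (`molecule`, `type`, `family`);
#'   defaults to the edge endpoints with type `"other"`.
#' @return A [KnowledgebaseGraph-class].
#' @export
knowledgebaseGraph <- function(edges, molecules = NULL) {
    if (is.null(molecules)) {
        ids <- sort(unique(c(edges[[1]], edges[[2]])))
        molecules <- data.frame(molecule = ids, type = "other",
                                family = NA_character_,
                                stringsAsFactors = FALSE)
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = molecules$molecule)
    new("KnowledgebaseGraph", graph = igraph::simplify(g),
        molecules = molecules)
}

#' Inject miRNA-target edges into a knowledgebase
#'
#' Adds one undirected edge per (confidence-passing) interaction record
#' whose endpoints both exist in the knowledgebase, so miRNAs can enter
#' networks through their targets.
#'
#' @param kb A [KnowledgebaseGraph-class].
#' @param records interaction records (columns `mirna_id`, `gene_id`).
#' @return The augmented [KnowledgebaseGraph-class].
#' @export
injectInteractions <- function(kb, records) {
    g <- kb@graph
    nms <- igraph::V(g)$name
    ok <- records$mirna_id %in% nms & records$gene_id %in% nms
    if (any(ok)) {
        ends <- rbind(records$mirna_id[ok], records$gene_id[ok])
        g <- igraph::simplify(igraph::add_edges(g, match(ends, nms)))
    }
    new("KnowledgebaseGraph", graph = g, molecules = kb@molecules)
}

## adjacency lookup: named list molecule -> neighbor molecule names
adjacencyList <- function(g) {
    adj <- igraph::as_adj_list(g)
    nms <- igraph::V(g)$name
    stats::setNames(lapply(adj, function(v) nms[as.integer(v)]), nms)
}

networkFromMembers <- function(members, focus, g, source, sizeLimit) {
    sub <- igraph::induced_subgraph(g, members)
    ed <- igraph::as_data_frame(sub, what = "edges")
    new("Network", molecules = members, focus = focus,
        edges = ed[order(ed$from, ed$to), , drop = FALSE],
        sourceDataset = source, sizeLimit = as.integer(sizeLimit))
}

#' Grow fixed-size high-connectivity networks from a dataset
#'
#' Greedy seed-and-grow reinterpretation of knowledgebase network
#' construction: dataset molecules present in the knowledgebase are the
#' focus molecules.  Each network is seeded with the unused focus
#' molecule having the most knowledgebase edges to other focus
#' molecules, then repeatedly extended by the best connected candidate.
#' Focus molecules are preferred: a connected focus candidate always
#' beats a non-focus one, so non-focus molecules enter only as
#' connectors when no focus molecule touches the current network.
#' Within that preference candidates are ranked by their number of
#' edges into the current network, then higher total knowledgebase
#' degree, then lexicographic id.  Growth stops at `size` molecules or
#' when no connected candidate remains.  Focus molecules consumed by one network are
#' unavailable to the dataset's later networks, so successive networks
#' are focus-disjoint and ranks are meaningful.  Each network is scored
#' with [networkScore()] and the list is ranked by descending score.
#'
#' @param datasetMolecules identifiers of the paired dataset's molecules
#'   (miRNAs and genes); unmapped ones are dropped with a warning.
#' @param kb A [KnowledgebaseGraph-class].
#' @param size network size cap (default 35 molecules).
#' @param nNetworks number of networks to derive (default 3).
#' @param sourceDataset label stored on each network.
#' @return list of [Network-class], ranked by score (rank 1 = highest).
#' @export
buildNetworks <- function(datasetMolecules, kb, size = 35, nNetworks = 3,
                          sourceDataset = "dataset") {
    g <- kb@graph
    nms <- igraph::V(g)$name
    datasetMolecules <- unique(datasetMolecules)
    focusAll <- intersect(datasetMolecules, nms)
    if (length(focusAll) < length(datasetMolecules))
        warning(length(datasetMolecules) - length(focusAll),
                " dataset molecules not in the knowledgebase were dropped")
    if (!length(focusAll)) {
        warning("no dataset molecule maps to the knowledgebase")
        return(list())
    }
    adj <- adjacencyList(g)
    deg <- stats::setNames(igraph::degree(g), nms)
    used <- character(0)
    nets <- list()
    for (b in seq_len(nNetworks)) {
        unused <- setdiff(focusAll, used)
        if (!length(unused)) break
        degToFocus <- vapply(unused, function(m)
            length(intersect(adj[[m]], focusAll)), integer(1))
        seed <- unused[order(-degToFocus, -deg[unused], unused)][1]
        members <- seed
        repeat {
            if (length(members) >= size) break
            cand <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                            c(members, used))
            if (!length(cand)) break
            edgesIn <- vapply(cand, function(m)
                length(intersect(adj[[m]], members)), integer(1))
            isFocus <- cand %in% focusAll
            pick <- cand[order(-isFocus, -edgesIn, -deg[cand], cand)][1]
            members <- c(members, pick)
        }
        focus <- intersect(members, focusAll)
        used <- union(used, focus)
        net <- networkFromMembers(members, focus, g, sourceDataset, size)
        net@score <- networkScore(net, datasetSizeInKb = length(focusAll),
                                  kbSize = length(nms))
        nets[[b]] <- net
    }
    if (!length(nets)) return(nets)
    ord <- order(-vapply(nets, function(n) n@score, numeric(1)))
    nets <- nets[ord]
    for (i in seq_along(nets)) nets[[i]]@rank <- i
    nets
}

#' Fisher-exact network score
#'
#' The score is `-log10` of the right-tailed Fisher exact (hypergeometric)
#' p-value for drawing at least `f` focus molecules when `|network|`
#' molecules are drawn from a knowledgebase of `kbSize` molecules of
#' which `datasetSizeInKb` belong to the dataset:
#' `P(X >= f), X ~ Hypergeometric(kbSize, datasetSizeInKb, |network|)`.
#'
#' @param network A [Network-class].
#' @param datasetSizeInKb number of dataset molecules mapped to the
#'   knowledgebase.
#' @param kbSize total number of knowledgebase molecules.
#' @return the score (`>= 0`).
#' @export
networkScore <- function(network, datasetSizeInKb, kbSize) {
    if (datasetSizeInKb > kbSize)
        stop("dataset size exceeds knowledgebase size")
    f <- length(network@focus)
    stopifnot(f <= min(length(network@molecules), datasetSizeInKb))
    p <- stats::phyper(f - 1, datasetSizeInKb, kbSize - datasetSizeInKb,
                       length(network@molecules), lower.tail = FALSE)
    -log10(p)
}

#' Grow a network by its most-connected candidate molecules
#'
#' Ranks candidate molecules by their number of knowledgebase edges into
#' the current network (ties broken by higher total knowledgebase
#' degree, then lexicographic id), adds the top `n` candidates having at
#' least one such edge, and reconnects the enlarged molecule set with
#' all knowledgebase edges among its members.  Used sequentially, e.g.
#' first with the ten best 0h DE targets and then the ten best 8h DE
#' targets.
#'
#' @param network A [Network-class].
#' @param candidates candidate molecule identifiers (e.g. a DE target
#'   set); unmapped or already-present molecules are ignored.
#' @param kb A [KnowledgebaseGraph-class].
#' @param n number of molecules to add (default 10).
#' @return The grown [Network-class] (size limit raised accordingly;
#'   score and rank retained from the parent network).
#' @export
growNetwork <- function(network, candidates, kb, n = 10) {
    g <- kb@graph
    nms <- igraph::V(g)$name
    adj <- adjacencyList(g)
    deg <- stats::setNames(igraph::degree(g), nms)
    cand <- setdiff(intersect(unique(candidates), nms), network@molecules)
    edgesIn <- vapply(cand, function(m)
        length(intersect(adj[[m]], network@molecules)), integer(1))
    cand <- cand[edgesIn >= 1]
    edgesIn <- edgesIn[edgesIn >= 1]
    add <- cand[order(-edgesIn, -deg[cand], cand)]
    add <- add[seq_len(min(n, length(add)))]
    members <- c(network@molecules, add)
    out <- networkFromMembers(members, network@focus, g,
                              network@sourceDataset,
                              max(network@sizeLimit, length(members)))
    out@score <- network@score
    out@rank <- network@rank
    out
}

#' Merge top networks and call critical network genes
#'
#' Merges the molecule sets of the top networks derived from the
#' 0h-miRNA and the 8h-miRNA paired datasets (each merged set expanded
#' so that any member of a gene family pulls in all same-family
#' molecules present in the dataset), then intersects: a critical
#' network gene is DE at 120 h and present in both merged networks.
#'
#' @param nets0h,nets8h lists of [Network-class] (typically the top 3 per
#'   dataset).
#' @param de120Genes genes DE at 120 h.
#' @param datasetMolecules molecules of the combined datasets, the
#'   universe for family expansion.
#' @param familyMap optional data.frame (`molecule`, `family`).
#' @return list with `merged_0h`, `merged_8h` (expanded molecule sets)
#'   and `critical` (sorted critical gene set).
#' @export
mergeAndCriticalGenes <- function(nets0h, nets8h, de120Genes,
                                  datasetMolecules, familyMap = NULL) {
    stopifnot(length(nets0h) > 0, length(nets8h) > 0)
    expand <- function(members) {
        if (is.null(familyMap) || !nrow(familyMap)) return(members)
        fams <- familyMap$family[familyMap$molecule %in% members]
        sibs <- familyMap$molecule[familyMap$family %in% fams]
        union(members, intersect(sibs, datasetMolecules))
    }
    m0 <- expand(unique(unlist(lapply(nets0h, function(n) n@molecules))))
    m8 <- expand(unique(unlist(lapply(nets8h, function(n) n@molecules))))
    list(merged_0h = sort(m0), merged_8h = sort(m8),
         critical = sort(intersect(intersect(de120Genes, m0), m8)))
}

#' Identify hub molecules across datasets
#'
#' Within each network, molecules are ranked by their within-network
#' degree (ties broken lexicographically); a molecule is a hub when it
#' ranks within the top `topK` by degree in networks derived from at
#' least two distinct source datasets.
#'
#' @param networks list of [Network-class] with `sourceDataset` set.
#' @param topK how many top-degree molecules per network count as highly
#'   connected (default 3).
#' @return data.frame with one row per hub: `molecule`, `n_datasets`,
#'   `datasets` (comma-separated), `max_degree`.
#' @export
findHubs <- function(networks, topK = 3) {
    empty <- data.frame(molecule = character(0), n_datasets = integer(0),
                        datasets = character(0), max_degree = integer(0))
    if (length(networks) == 0 ||
        length(unique(vapply(networks, function(n) n@sourceDataset,
                             character(1)))) < 2) {
        warning("hub identification needs networks from >= 2 datasets; no hubs called")
        return(empty)
    }
    hits <- list()
    for (net in networks) {
        if (!nrow(net@edges)) next
        degs <- table(c(net@edges$from, net@edges$to))
        ord <- order(-as.integer(degs), names(degs))
        top <- names(degs)[ord][seq_len(min(topK, length(degs)))]
        hits[[length(hits) + 1L]] <- data.frame(
            molecule = top, dataset = net@sourceDataset,
            degree = as.integer(degs[top]), stringsAsFactors = FALSE)
    }
    if (!length(hits)) return(empty)
    hits <- do.call(rbind, hits)
    agg <- split(hits, hits$molecule)
    out <- do.call(rbind, lapply(agg, function(h) data.frame(
        molecule = h$molecule[1],
        n_datasets = length(unique(h$dataset)),
        datasets = paste(sort(unique(h$dataset)), collapse = ","),
        max_degree = max(h$degree), stringsAsFactors = FALSE)))
    out <- out[out$n_datasets >= 2, , drop = FALSE]
    out <- out[order(-out$n_datasets, -out$max_degree, out$molecule), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Fisher-exact gene-set enrichment
#'
#' Right-tailed Fisher exact test on the 2x2 table of membership in the
#' dataset versus membership in the gene set over a common universe.
#'
#' @param datasetGenes genes in the analyzed dataset (subset of
#'   `universe`).
#' @param geneSet the gene set (subset of `universe`).
#' @param universe the reference gene universe (non-empty).
#' @return list with `odds_ratio` (conditional MLE), `p` and the 2x2
#'   `table`.
#' @export
geneSetEnrichment <- function(datasetGenes, geneSet, universe) {
    if (!length(universe)) stop("empty universe")
    universe <- unique(universe)
    datasetGenes <- intersect(unique(datasetGenes), universe)
    geneSet <- intersect(unique(geneSet), universe)
    a <- length(intersect(datasetGenes, geneSet))
    b <- length(datasetGenes) - a
    cc <- length(geneSet) - a
    dd <- length(universe) - a - b - cc
    tab <- matrix(c(a, b, cc, dd), 2, 2,
                  dimnames = list(inDataset = c("yes", "no"),
                                  inSet = c("yes", "no")))
    ft <- stats::fisher.test(tab, alternative = "greater")
    list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Directional consistency z-score
#'
#' A simplified consistency score for a functional annotation: with
#' `c` genes whose observed DE direction matches the annotation's
#' expected direction and `i` genes opposing it,
#' `z = (c - i) / sqrt(c + i)`.  Genes without an expected or observed
#' sign are excluded; with none left the score is `NA`.  This is a
#' sign-consistency summary, not a causal regulator score.
#'
#' @param expected named numeric vector of expected signs (+1/-1; 0 or
#'   `NA` to exclude).
#' @param observed named numeric vector of observed DE signs.
#' @return the z-score, or `NA` when no gene carries both signs.
#' @export
directionZscore <- function(expected, observed) {
    common <- intersect(names(expected), names(observed))
    e <- sign(expected[common]); o <- sign(observed[common])
    ok <- !is.na(e) & !is.na(o) & e != 0 & o != 0
    if (!any(ok)) return(NA_real_)
    cons <- sum(e[ok] == o[ok]); incons <- sum(e[ok] != o[ok])
    (cons - incons) / sqrt(cons + incons)
}
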