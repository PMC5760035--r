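#' Center and scale temporal profiles
#'
#' Each profile (row; one log2 treated/control ratio per time point) is
#' centered to mean zero and scaled to unit sample standard deviation
#' (`n - 1` denominator).  Constant profiles map to all-zero with a
#' warning; missing values are an error naming the profile.
#'
#' @param x numeric matrix, profiles in rows, time points in columns.
#' @return matrix of the same shape with scaled rows.
#' @export
scaleProfiles <- function(x) {
    x <- as.matrix(x)
    bad <- rownames(x)[!stats::complete.cases(x)]
    if (length(bad))
        stop("profiles with missing time points: ",
             paste(bad, collapse = ", "))
    m <- rowMeans(x)
    s <- apply(x, 1, stats::sd)
    if (any(s == 0))
        warning(sum(s == 0), " constant profile(s) scaled to all-zero")
    out <- (x - m) / ifelse(s == 0, 1, s)
    out[s == 0, ] <- 0
    out
}

## Deterministic agglomerative clustering (Lance-Williams updates).
## Ties in the minimum inter-cluster distance are broken by the lowest
## pair of cluster labels, a cluster's label being the smallest original
## row index among its members.  Ward follows the squared-distance
## (Ward.D2-style) update with heights on the distance scale.
agglomerate <- function(x, linkage = c("average", "complete", "ward")) {
    linkage <- match.arg(linkage)
    n <- nrow(x)
    d <- as.matrix(stats::dist(x))
    if (linkage == "ward") d <- d^2
    diag(d) <- Inf
    size <- rep(1L, n)
    label <- seq_len(n)
    active <- rep(TRUE, n)
    merges <- vector("list", n - 1L)
    heights <- numeric(n - 1L)
    parent <- seq_len(n)               # member -> current cluster slot
    for (step in seq_len(n - 1L)) {
        dm <- min(d[active, active])
        ## all active index pairs achieving the minimum
        hit <- which(d == dm & outer(active, active, `&`), arr.ind = TRUE)
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        lab <- cbind(pmin(label[hit[, 1]], label[hit[, 2]]),
                     pmax(label[hit[, 1]], label[hit[, 2]]))
        pick <- order(lab[, 1], lab[, 2])[1]
        i <- hit[pick, 1]; j <- hit[pick, 2]
        heights[step] <- if (linkage == "ward") sqrt(dm) else dm
        merges[[step]] <- c(i, j)
        others <- which(active); others <- others[!others %in% c(i, j)]
        for (o in others) {
            d[i, o] <- d[o, i] <- switch(linkage,
                average = (size[i] * d[i, o] + size[j] * d[j, o]) /
                          (size[i] + size[j]),
                complete = max(d[i, o], d[j, o]),
                ward = ((size[i] + size[o]) * d[i, o] +
                        (size[j] + size[o]) * d[j, o] -
                        size[o] * d[i, j]) / (size[i] + size[j] + size[o]))
        }
        size[i] <- size[i] + size[j]
        label[i] <- min(label[i], label[j])
        active[j] <- FALSE
        parent[parent == j] <- i
    }
    list(merges = merges, heights = heights, n = n)
}

## Cut a deterministic agglomeration at k clusters: replay the first
## n - k merges and renumber clusters by first occurrence.
cutAgglomeration <- function(tree, k) {
    n <- tree$n
    stopifnot(k >= 1, k <= n)
    slot <- seq_len(n)
    for (step in seq_len(n - k)) {
        ij <- tree$merges[[step]]
        slot[slot == ij[2]] <- ij[1]
    }
    as.integer(factor(slot, levels = unique(slot)))
}

#' Cluster temporal profiles with a fixed algorithm and cluster count
#'
#' Euclidean distance on the (already scaled) profiles.  The
#' hierarchical linkages (average, complete, Ward) use a deterministic
#' agglomeration whose distance ties are broken by the lowest pair of
#' cluster labels; k-means uses Ward-cut centroids as initial centers,
#' making it deterministic as well.
#'
#' @param x scaled profile matrix (rows = profiles).
#' @param algorithm one of `"hierarchical-average"`,
#'   `"hierarchical-complete"`, `"hierarchical-ward"`, `"kmeans"`.
#' @param k number of clusters, `2 <= k <= nrow(x) - 1`.
#' @param L neighbor count for the connectivity measure (default 10).
#' @return A [ClusterSolution-class].
#' @export
clusterProfiles <- function(x, algorithm = c("hierarchical-average",
                                             "hierarchical-complete",
                                             "hierarchical-ward",
                                             "kmeans"),
                            k, L = 10) {
    algorithm <- match.arg(algorithm)
    x <- as.matrix(x)
    n <- nrow(x)
    if (k < 2) stop("k must be at least 2")
    if (k > n - 1) stop("k = ", k, " exceeds n - 1 = ", n - 1)
    if (algorithm == "kmeans") {
        init <- cutAgglomeration(agglomerate(x, "ward"), k)
        centers <- apply(x, 2, function(col) tapply(col, init, mean))
        assign <- tryCatch({
            km <- stats::kmeans(x, centers = centers, iter.max = 100)
            as.integer(km$cluster)
        }, error = function(e) init)   # duplicate centers: keep Ward cut
        if (length(unique(assign)) < k) assign <- init
    } else {
        linkage <- sub("hierarchical-", "", algorithm)
        assign <- cutAgglomeration(agglomerate(x, linkage), k)
    }
    assign <- as.integer(factor(assign, levels = unique(assign)))
    names(assign) <- rownames(x)
    meas <- validationMeasures(x, assign, L = L)
    new("ClusterSolution", algorithm = algorithm, k = as.integer(k),
        assignment = assign, measures = meas)
}

#' Internal cluster validation measures
#'
#' Connectivity: for each point, its `L` nearest neighbors in order
#' contribute `1/j` (for the `j`-th neighbor) whenever that neighbor lies
#' outside the point's cluster; lower is better, 0 when every neighbor
#' list stays within its cluster.  Dunn index: smallest between-cluster
#' point distance divided by the largest within-cluster diameter; higher
#' is better.  Silhouette: mean over points of `(b - a)/max(a, b)` where
#' `a` is the mean distance to the point's own cluster and `b` the
#' smallest mean distance to another cluster; points in singleton
#' clusters contribute 0 by convention.
#'
#' @param x scaled profile matrix.
#' @param assignment integer cluster ids (1..k).
#' @param L neighbor count for connectivity; truncated to `n - 1`.
#' @return named numeric vector `connectivity`, `dunn`, `silhouette`.
#' @export
validationMeasures <- function(x, assignment, L = 10) {
    x <- as.matrix(x)
    n <- nrow(x)
    stopifnot(length(assignment) == n)
    k <- length(unique(assignment))
    if (k < 2) stop("validation measures need at least 2 clusters")
    dm <- as.matrix(stats::dist(x))
    L <- min(L, n - 1)

    ## connectivity (neighbor ties resolved by row index for determinism)
    conn <- 0
    for (i in seq_len(n)) {
        nb <- order(dm[i, -i])         # indices within the reduced vector
        idx <- seq_len(n)[-i][nb][seq_len(L)]
        out <- assignment[idx] != assignment[i]
        conn <- conn + sum((1 / seq_len(L))[out])
    }

    ## Dunn index
    same <- outer(assignment, assignment, `==`)
    diag(same) <- NA
    inter <- dm[!same & !is.na(same)]
    intra <- dm[same & !is.na(same)]
    maxDiam <- if (length(intra)) max(intra) else 0
    dunn <- if (maxDiam > 0) min(inter) / maxDiam else Inf

    ## silhouette
    s <- numeric(n)
    sizes <- table(assignment)
    for (i in seq_len(n)) {
        ci <- assignment[i]
        if (sizes[[as.character(ci)]] == 1) { s[i] <- 0; next }
        a <- mean(dm[i, assignment == ci & seq_len(n) != i])
        b <- min(vapply(setdiff(unique(assignment), ci), function(cj)
            mean(dm[i, assignment == cj]), numeric(1)))
        s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    c(connectivity = conn, dunn = dunn, silhouette = mean(s))
}

#' Select the best clustering over algorithms and cluster counts
#'
#' Evaluates every (algorithm, k) combination, ranks the solutions per
#' validation measure (connectivity ascending; Dunn and silhouette
#' descending) and returns the solution with the best mean rank.  Ties
#' are broken toward the smaller k, then the earlier algorithm in
#' `algorithms`.
#'
#' @param x scaled profile matrix.
#' @param algorithms candidate algorithms, in preference order.
#' @param kRange candidate cluster counts (values above `nrow(x) - 1`
#'   are dropped).
#' @param L neighbor count for connectivity.
#' @return The winning [ClusterSolution-class]; its `grid` slot holds
#'   the full evaluation table (algorithm, k, the three measures, mean
#'   rank).
#' @export
selectSolution <- function(x, algorithms = c("hierarchical-average",
                                             "hierarchical-complete",
                                             "hierarchical-ward",
                                             "kmeans"),
                           kRange = 2:8, L = 10) {
    x <- as.matrix(x)
    kRange <- kRange[kRange >= 2 & kRange <= nrow(x) - 1]
    if (!length(kRange)) stop("no valid k in kRange for ", nrow(x), " profiles")
    sols <- list(); rows <- list()
    for (alg in algorithms) for (k in kRange) {
        sol <- clusterProfiles(x, alg, k, L = L)
        sols[[length(sols) + 1L]] <- sol
        rows[[length(rows) + 1L]] <- data.frame(
            algorithm = alg, k = k,
            connectivity = sol@measures[["connectivity"]],
            dunn = sol@measures[["dunn"]],
            silhouette = sol@measures[["silhouette"]],
            stringsAsFactors = FALSE)
    }
    grid <- do.call(rbind, rows)
    grid$mean_rank <- (rank(grid$connectivity) + rank(-grid$dunn) +
                       rank(-grid$silhouette)) / 3
    algOrder <- match(grid$algorithm, algorithms)
    best <- order(grid$mean_rank, grid$k, algOrder)[1]
    winner <- sols[[best]]
    winner@grid <- grid
    winner
}
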