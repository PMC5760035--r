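## Independent brute-force oracles and small fixture builders.

## Benjamini-Hochberg by the step-up definition, element by element.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(ps[i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

## Right-tail hypergeometric probability by explicit summation.
bruteHyperTail <- function(f, F, N, k) {
    js <- f:min(k, F)
    sum(choose(F, js) * choose(N - F, k - js)) / choose(N, k)
}

## Validation measures by plain loops over an explicit distance matrix.
bruteMeasures <- function(x, assign, L = 10) {
    n <- nrow(x)
    dm <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
        dm[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    L <- min(L, n - 1)
    conn <- 0
    for (i in 1:n) {
        nb <- setdiff(order(dm[i, ]), i)[1:L]
        for (j in 1:L)
            if (assign[nb[j]] != assign[i]) conn <- conn + 1 / j
    }
    inter <- Inf; intra <- 0
    for (i in 1:n) for (j in 1:n) {
        if (i == j) next
        if (assign[i] == assign[j]) intra <- max(intra, dm[i, j])
        else inter <- min(inter, dm[i, j])
    }
    dunn <- if (intra > 0) inter / intra else Inf
    s <- numeric(n)
    for (i in 1:n) {
        own <- which(assign == assign[i] & seq_len(n) != i)
        if (!length(own)) { s[i] <- 0; next }
        a <- mean(dm[i, own])
        b <- Inf
        for (cl in setdiff(unique(assign), assign[i]))
            b <- min(b, mean(dm[i, assign == cl]))
        s[i] <- (b - a) / max(a, b)
    }
    c(connectivity = conn, dunn = dunn, silhouette = mean(s))
}

## Average-linkage agglomeration with distances recomputed from scratch
## (mean over all original point pairs), O(n^3); returns merge heights.
bruteAverageHeights <- function(x) {
    n <- nrow(x)
    dm <- as.matrix(dist(x))
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- Inf; bi <- bj <- 0
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (i >= j) next
            d <- mean(dm[clusters[[i]], clusters[[j]]])
            if (d < best) { best <- d; bi <- i; bj <- j }
        }
        heights <- c(heights, best)
        clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
        clusters[[bj]] <- NULL
    }
    heights
}

## Minimal ExpressionDataset from a matrix, with uniform metadata.
toyDataset <- function(x, detp = NULL, region = "AMY", time_h = 0,
                       condition = NULL, species = "mouse",
                       maturity = "mature") {
    n <- ncol(x)
    if (is.null(detp)) detp <- matrix(0, nrow(x), n)
    if (is.null(condition))
        condition <- rep(c("treated", "control"), length.out = n)
    rownames(x) <- rownames(detp) <- sprintf("p%03d", seq_len(nrow(x)))
    colnames(x) <- colnames(detp) <- sprintf("s%03d", seq_len(n))
    ExpressionDataset(x, detp,
        data.frame(sample_id = colnames(x), region = region,
                   time_h = time_h, condition = condition,
                   animal_id = sprintf("a%03d", seq_len(n))),
        data.frame(probe_id = rownames(x),
                   species = rep_len(species, nrow(x)),
                   maturity = rep_len(maturity, nrow(x)),
                   annotation = sprintf("ann%03d", seq_len(nrow(x)))))
}

## Small, fast simulation configuration for structural tests.
smallConfig <- function(seed, ...) {
    defaults <- list(seed = seed, nRegions = 1L, nMirnaProbes = 150L,
                     nMrnaProbes = 500L, nDeMirnaPerTime = 6L,
                     kbNMolecules = 800L, nOutlierSamples = 0L,
                     noiseSd = 0.1)
    args <- utils::modifyList(defaults, list(...))
    do.call(simulationConfig, args)
}
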