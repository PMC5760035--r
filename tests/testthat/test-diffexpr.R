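makeContrastDs <- function(trt, ctl) {
    x <- rbind(c(trt, ctl))
    toyDataset(x, matrix(0, 1, length(c(trt, ctl))),
               condition = rep(c("treated", "control"),
                               c(length(trt), length(ctl))))
}

test_that("group-mean fits reproduce the hand-computed pooled statistics", {
    ds <- makeContrastDs(c(8.1, 8.3, 8.2, 8.4), c(8.0, 8.1, 7.9, 8.0))
    fit <- fitGroupMeans(ds, "AMY", 0)
    expect_equal(fit$beta, 0.25)
    expect_equal(fit$s2, (0.05 + 0.02) / 6)   # pooled SS by hand
    expect_equal(fit$d, 6)
    expect_equal(fit$v, 0.5)

    ## treated == control -> beta 0
    ds0 <- makeContrastDs(c(1, 2, 3), c(1, 2, 3))
    expect_equal(fitGroupMeans(ds0, "AMY", 0)$beta, 0)

    ## doubling values doubles beta and quadruples s2
    ds2 <- makeContrastDs(2 * c(8.1, 8.3, 8.2, 8.4),
                          2 * c(8.0, 8.1, 7.9, 8.0))
    fit2 <- fitGroupMeans(ds2, "AMY", 0)
    expect_equal(fit2$beta, 2 * fit$beta)
    expect_equal(fit2$s2, 4 * fit$s2)

    ## too-small group errors naming the contrast
    ds3 <- makeContrastDs(c(8.1), c(8.0, 8.1, 7.9))
    expect_error(fitGroupMeans(ds3, "AMY", 0), "AMY/0h")
})

test_that("hyperparameter estimation satisfies its own moment equations", {
    set.seed(5)
    s2 <- 0.05 * rf(10, df1 = 14, df2 = 4)
    h <- estimateHyperparameters(s2, 14)
    expect_gt(h@d0, 0)
    expect_true(is.finite(h@d0))
    ## the trigamma equation holds at the returned d0 (Newton tol 1e-8)
    e <- log(s2) - digamma(14 / 2) + log(14 / 2)
    evar <- var(e) - trigamma(14 / 2)
    expect_equal(trigamma(h@d0 / 2), evar, tolerance = 1e-7)
    expect_equal(h@s0Sq,
                 exp(mean(e) + digamma(h@d0 / 2) - log(h@d0 / 2)))

    ## identical variances -> infinite prior df, full shrinkage
    expect_warning(h2 <- estimateHyperparameters(c(rep(0.3, 20), 0), 14),
                   "zero variances")
    expect_true(is.infinite(h2@d0))
    e2 <- log(0.3) - digamma(7) + log(7)
    expect_equal(h2@s0Sq, exp(e2))
    mt <- moderatedT(rep(0.1, 3), rep(0.3, 3), 14, 0.25, h2)
    expect_equal(mt$s2_post, rep(h2@s0Sq, 3))

    expect_error(estimateHyperparameters(rep(0.1, 5), 14), ">= 10 probes")
})

test_that("moderated t matches limma's empirical-Bayes fit", {
    set.seed(31)
    x <- matrix(rnorm(200 * 16, 8, 0.4), 200, 16)
    design <- cbind(intercept = 1, trt = rep(c(1, 0), each = 8))
    eb <- limma::eBayes(limma::lmFit(x, design))
    xt <- x[, 1:8]; xc <- x[, 9:16]
    beta <- rowMeans(xt) - rowMeans(xc)
    s2 <- (rowSums((xt - rowMeans(xt))^2) +
           rowSums((xc - rowMeans(xc))^2)) / 14
    h <- estimateHyperparameters(s2, 14)
    expect_equal(h@d0, eb$df.prior, tolerance = 1e-10)
    expect_equal(h@s0Sq, eb$s2.prior, tolerance = 1e-10)
    mt <- moderatedT(beta, s2, 14, 0.25, h)
    expect_equal(mt$t_mod, unname(eb$t[, "trt"]), tolerance = 1e-12)
    expect_equal(mt$p, unname(eb$p.value[, "trt"]), tolerance = 1e-12)
    ## invariant: posterior variance lies between s2 and s0^2
    expect_true(all(mt$s2_post >= pmin(s2, h@s0Sq) - 1e-15 &
                    mt$s2_post <= pmax(s2, h@s0Sq) + 1e-15))
})

test_that("moderated t has the stated limiting forms and monotonicity", {
    set.seed(6)
    beta <- rnorm(50, 0, 0.2)
    s2 <- 0.04 * rchisq(50, 14) / 14
    v <- 0.25; d <- 14; s0 <- 0.05
    ## d0 = Inf: t = beta / sqrt(s0^2 v), normal tail
    hInf <- new("EBayesHyper", d0 = Inf, s0Sq = s0)
    mtInf <- moderatedT(beta, s2, d, v, hInf)
    expect_equal(mtInf$t_mod, beta / sqrt(s0 * v))
    expect_equal(mtInf$p, 2 * pnorm(abs(beta / sqrt(s0 * v)),
                                    lower.tail = FALSE))
    ## beta = 0 -> t = 0, p = 1
    mt0 <- moderatedT(0, 0.1, d, v, hInf)
    expect_equal(mt0$t_mod, 0)
    expect_equal(mt0$p, 1)
    ## increasing d0 moves every t monotonically toward the d0=Inf limit
    d0grid <- c(0, 1, 4, 16, 64, 256)
    tmat <- sapply(d0grid, function(d0) moderatedT(
        beta, s2, d, v, new("EBayesHyper", d0 = d0, s0Sq = s0))$t_mod)
    gap <- abs(tmat - mtInf$t_mod)
    expect_true(all(diff(t(gap)) <= 1e-12))
})

test_that("BH adjustment follows the step-up definition", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
    set.seed(8)
    for (r in 1:25) {
        m <- sample(1:12, 1)
        p <- round(runif(m), 3)
        q <- bhFdr(p)
        expect_equal(q, bruteBH(p))
        expect_true(all(q >= p))
        ## permutation invariance
        perm <- sample(m)
        expect_equal(bhFdr(p[perm]), q[perm])
    }
})

test_that("signed linear fold change uses the reporting convention", {
    expect_equal(signedFoldChange(0), 1)
    expect_equal(signedFoldChange(1), 2)
    expect_equal(signedFoldChange(-1), -2)
    ## a treated/control ratio of 1/1.35 reports as -1.35
    expect_equal(signedFoldChange(log2(1 / 1.35)), -1.35)
})

test_that("DE calls apply the role- and time-specific thresholds", {
    tab <- data.frame(
        probe_id = c("a", "b", "c", "d", "d2"),
        annotation = c("A", "B", "C", "D", "D"),
        region = "AMY",
        time_h = c(8, 120, 0, 120, 120),
        logFC = 0.1, fc_signed = 1.07, t_mod = 2,
        p = c(0.01, 0.049, 0.03, 0.03, 0.20),
        fdr = c(0.08, 0.40, 0.04, 0.30, 0.90))
    mr <- callDE(tab, "mrna")
    expect_false(mr$table$is_de[1])  # 8h needs FDR <= 0.05
    expect_true(mr$table$is_de[2])   # 120h nominal p <= 0.05 suffices
    expect_true(mr$table$is_de[3])   # 0h, fdr 0.04
    ## duplicate probes resolved by minimum p at the annotation level
    drow <- mr$byAnnotation[mr$byAnnotation$annotation == "D", ]
    expect_equal(nrow(drow), 1)
    expect_equal(drow$p, 0.03)
    ## miRNAs use the nominal threshold at every time
    mi <- callDE(tab, "mirna")
    expect_true(all(mi$table$is_de == (tab$p <= 0.05)))
    expect_error(callDE(tab, "protein"), "arg")
})

test_that("planted miRNA effects of |FC| 1.4 are detected with >= 90% power", {
    hits <- 0; total <- 0
    for (s in 1:20) {
        cfg <- smallConfig(seed = 300 + s, noiseSd = 0.25,
                           mirnaFcRange = c(1.4, 1.4))
        sim <- simulateExpression(cfg)
        de <- runDE(sim$mirna, "AMY")
        called <- callDE(de, "mirna")
        dm <- sim$truth@deMirnas
        key <- paste(called$table$probe_id, called$table$time_h)
        deKey <- key[called$table$is_de]
        hits <- hits + sum(paste(dm$probe, dm$time_h) %in% deKey)
        total <- total + nrow(dm)
    }
    expect_gte(hits / total, 0.90)
})
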