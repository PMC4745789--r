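rankedVec <- function(metric, ids = sprintf("g%03d", seq_along(metric))) {
    data.frame(gene_id = ids, metric = sort(metric, decreasing = TRUE))
}

test_that("per-gene metric is the maximum over linked enhancers", {
    enh <- GRanges("chr1", IRanges(c(1, 40001, 80001), width = 2000))
    tr <- SignalTrack(GRanges("chr1", ranges(enh), score = c(9, 3, 1) / 2000))
    rk <- callSuperEnhancers(quantifyEnhancers(enh, tr), "top_n", n = 1)
    ## one gene within 50 kb of the signal-9 and signal-3 enhancers
    genes <- GRanges("chr1", IRanges(c(30000, 81000), width = 1),
                     gene_id = c("gA", "gB"), expression = c(5, 5))
    a <- assignGenes(rk, genes, windowBp = 50000)
    ranked <- rankGenesByEnhancerSignal(a, rk)
    expect_equal(ranked$gene_id, c("gA", "gB"))
    expect_equal(ranked$metric, c(9, 3), tolerance = 1e-9)
})

test_that("enrichment score matches the spec'd extremes", {
    r <- rankedVec(10:1)
    ## singleton set at the very top: es hits 1 at position 1
    es1 <- enrichmentScore(r, "g001", weightExponent = 1)
    expect_equal(es1$es, 1)
    expect_equal(es1$running_sum[1], 1)
    ## the full list: all increments, no decrements
    esAll <- enrichmentScore(r, r$gene_id, weightExponent = 1)
    expect_equal(esAll$es, 1)
    expect_error(enrichmentScore(r, "absent"), "disjoint")
})

test_that("enrichment score equals a step-by-step loop oracle on short lists", {
    withr::local_seed(101)
    for (rep in 1:200) {
        n <- sample(3:10, 1)
        metric <- sort(round(rexp(n, 0.2), 3), decreasing = TRUE)
        r <- rankedVec(metric)
        s <- sample(1:(n - 1), 1)
        set <- sample(r$gene_id, s)
        hit <- r$gene_id %in% set
        for (w in c(0, 1)) {
            got <- enrichmentScore(r, set, w)$es
            expect_equal(got, loopEnrichmentScore(r$metric, hit, w),
                         tolerance = 1e-12)
        }
    }
})

test_that("weight-0 running sums end at zero and are metric-transform invariant", {
    withr::local_seed(103)
    for (rep in 1:20) {
        n <- sample(20:100, 1)
        r <- rankedVec(sort(runif(n, 0, 50), decreasing = TRUE))
        set <- sample(r$gene_id, sample(2:(n %/% 2), 1))
        es <- enrichmentScore(r, set, 0)
        expect_equal(es$running_sum[n], 0, tolerance = 1e-12)
        ## strictly monotone transform leaves the weight-0 es unchanged
        r2 <- r
        r2$metric <- exp(r2$metric / 25)
        expect_equal(enrichmentScore(r2, set, 0)$es, es$es,
                     tolerance = 1e-12)
    }
})

test_that("permutation p-values are reproducible, bounded, and detect a top set", {
    withr::local_seed(107)
    n <- 1000
    r <- rankedVec(sort(rexp(n, 0.05), decreasing = TRUE))
    topset <- r$gene_id[1:100]
    g1 <- gseaPermutation(r, topset, nPermutations = 999, seed = 5)
    g2 <- gseaPermutation(r, topset, nPermutations = 999, seed = 5)
    expect_identical(g1, g2)
    expect_lte(g1$p_value, 0.01)
    expect_gt(g1$p_value, 0)
    expect_lte(g1$p_value, 1)
    expect_equal(g1$es, max(abs(g1$running_sum)) * sign(g1$es))
    expect_error(gseaPermutation(r, topset, nPermutations = 50), "at least 100")
    expect_error(gseaPermutation(r, r$gene_id, nPermutations = 200),
                 "smaller than the list")
})

test_that("the weighted statistic agrees with an independent GSEA implementation", {
    withr::local_seed(109)
    for (rep in 1:20) {
        n <- sample(50:300, 1)
        stats <- sort(rexp(n), decreasing = TRUE)
        r <- rankedVec(stats)
        idx <- sort(sample(n, sample(3:20, 1)))
        mine <- enrichmentScore(r, r$gene_id[idx], weightExponent = 1)$es
        ref <- fgsea::calcGseaStat(stats, selectedStats = idx, gseaParam = 1)
        expect_equal(mine, ref, tolerance = 1e-9)
    }
})

test_that("expression comparison between classes uses a one-sided rank test", {
    enh <- GRanges("chr1", IRanges(c(1, 200001), width = 2000))
    tr <- SignalTrack(GRanges("chr1", ranges(enh), score = c(5, 0.5)))
    rk <- callSuperEnhancers(quantifyEnhancers(enh, tr), "top_n", n = 1)
    mk <- function(exprS, exprT) {
        ns <- length(exprS); nt <- length(exprT)
        GRanges("chr1", IRanges(c(seq(3000, by = 10, length.out = ns),
                                  seq(203000, by = 10, length.out = nt)),
                                width = 1),
                gene_id = sprintf("g%02d", seq_len(ns + nt)),
                expression = c(exprS, exprT))
    }
    ## SUPER values all above TYPICAL: exact one-sided p = 1/C(10,5)
    g <- mk(c(10, 11, 12, 13, 14) + 0.1, c(1, 2, 3, 4, 5))
    a <- assignGenes(rk, g, windowBp = 50000, expressionThreshold = 0)
    r <- expressionByClass(g, a)
    expect_equal(r$p_value, 1 / choose(10, 5))
    expect_equal(r$super$n, 5)
    expect_equal(r$typical$median, 3)

    ## identical distributions: one-sided p at least 0.5
    g2 <- mk(c(1.5, 2.5, 3.5, 4.5), c(1.5, 2.5, 3.5, 4.5) + 1e-4)
    a2 <- assignGenes(rk, g2, windowBp = 50000, expressionThreshold = 0)
    expect_gte(expressionByClass(g2, a2)$p_value, 0.44)

    ## single gene per class: quartiles collapse, no test
    g3 <- mk(7, 3)
    a3 <- assignGenes(rk, g3, windowBp = 50000, expressionThreshold = 0)
    r3 <- expressionByClass(g3, a3)
    expect_true(is.na(r3$p_value))
    expect_equal(r3$super$q1, 7)
    expect_equal(r3$super$q3, 7)
})
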