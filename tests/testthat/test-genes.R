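## a classified two-enhancer ranking: one SUPER at 100k, one TYPICAL at 400k
demoRanking <- function() {
    enh <- GRanges("chr1", IRanges(c(100001, 400001), width = c(30000, 2000)))
    tr <- SignalTrack(GRanges("chr1",
        IRanges(c(100001, 400001), width = c(30000, 2000)),
        score = c(5, 0.5)))
    callSuperEnhancers(quantifyEnhancers(enh, tr), "top_n", n = 1)
}

mkGenes <- function(pos, expr, chrom = "chr1") {
    GRanges(chrom, IRanges(pos, width = 1),
            gene_id = sprintf("g%03d", seq_along(pos)),
            expression = expr)
}

test_that("genes link to enhancers within the window, filtered by expression", {
    rk <- demoRanking()
    ## TSS 10 kb left of the SUPER boundary
    genes <- mkGenes(c(90000, 200000, 30000), c(5, 5, 5))
    a <- assignGenes(rk, genes, windowBp = 50000)
    links <- as.data.frame(assignmentLinks(a))
    expect_true("g001" %in% links$gene_id)
    expect_equal(links$distance[links$gene_id == "g001"], 10000)
    ## 60 kb away: not linked (SUPER spans 100001-130000; g002 at 200000
    ## is 69999 bp from the right edge)
    expect_false("g002" %in% links$gene_id)
    ## below the expression threshold: not linked even when close
    lowexpr <- mkGenes(90001, 0.5)
    a2 <- assignGenes(rk, lowexpr, windowBp = 50000,
                      expressionThreshold = 1)
    expect_equal(nrow(assignmentLinks(a2)), 0)
    ## TSS inside the enhancer: distance 0
    inside <- mkGenes(110000, 5)
    a3 <- assignGenes(rk, inside, windowBp = 50000)
    expect_equal(as.data.frame(assignmentLinks(a3))$distance, 0)
})

test_that("assignment links equal an exhaustive pairwise oracle", {
    withr::local_seed(67)
    n_enh <- 50
    enh <- GRanges("chr1", IRanges(seq(1, by = 60000, length.out = n_enh),
                                   width = sample(1000:20000, n_enh)))
    tr <- SignalTrack(GRanges("chr1", ranges(enh),
                              score = runif(n_enh, 0.1, 5)))
    rk <- callSuperEnhancers(quantifyEnhancers(enh, tr), "top_n", n = 5)
    genes <- mkGenes(sample.int(3.2e6, 200), round(rlnorm(200, 0, 1), 3))
    a <- assignGenes(rk, genes, windowBp = 50000, expressionThreshold = 1)
    links <- as.data.frame(assignmentLinks(a))
    egr <- enhancerRegions(rk)
    want <- list()
    for (i in seq_along(genes)) {
        if (genes$expression[i] < 1) next
        for (j in seq_along(egr)) {
            gap <- max(0, max(start(egr)[j], start(genes)[i]) -
                          min(end(egr)[j], start(genes)[i]) - 1)
            inside <- start(genes)[i] >= start(egr)[j] &&
                start(genes)[i] <= end(egr)[j]
            d <- if (inside) 0 else gap
            if (d <= 50000)
                want[[length(want) + 1L]] <- paste(egr$enhancer_id[j],
                                                   genes$gene_id[i], d)
        }
    }
    got <- paste(links$enhancer_id, links$gene_id, links$distance)
    expect_setequal(got, unlist(want))
})

test_that("shrinking the window never adds links", {
    withr::local_seed(71)
    enh <- GRanges("chr1", IRanges(seq(1, by = 80000, length.out = 20),
                                   width = 5000))
    tr <- SignalTrack(GRanges("chr1", ranges(enh), score = runif(20, 1, 5)))
    rk <- callSuperEnhancers(quantifyEnhancers(enh, tr), "top_n", n = 3)
    genes <- mkGenes(sample.int(1.7e6, 100), rep(5, 100))
    prev <- Inf
    for (w in sort(round(runif(50, 0, 80000)), decreasing = TRUE)) {
        n <- nrow(assignmentLinks(assignGenes(rk, genes, windowBp = w)))
        expect_lte(n, prev)
        prev <- n
    }
})

test_that("class gene sets are disjoint with SUPER precedence", {
    rk <- demoRanking()
    ## one gene near both enhancers is impossible here; craft links by
    ## placing one gene between two enhancers of different class
    enh <- GRanges("chr1", IRanges(c(1, 60001), width = c(2000, 2000)))
    tr <- SignalTrack(GRanges("chr1", ranges(enh), score = c(5, 0.5)))
    rk2 <- callSuperEnhancers(quantifyEnhancers(enh, tr), "top_n", n = 1)
    gene <- mkGenes(31000, 5)   # within 50 kb of both
    a <- assignGenes(rk2, gene, windowBp = 50000)
    cs <- classGeneSets(a)
    expect_equal(cs$super_genes, "g001")
    expect_length(cs$typical_genes, 0)

    ## no links -> both empty
    farGene <- mkGenes(3000000, 5)
    cs0 <- classGeneSets(assignGenes(rk2, farGene, windowBp = 1000))
    expect_length(cs0$super_genes, 0)
    expect_length(cs0$typical_genes, 0)
})

test_that("the partition is disjoint and covers exactly the linked genes", {
    withr::local_seed(73)
    for (rep in 1:10) {
        n_enh <- 30
        enh <- GRanges("chr1", IRanges(seq(1, by = 40000, length.out = n_enh),
                                       width = 3000))
        tr <- SignalTrack(GRanges("chr1", ranges(enh),
                                  score = runif(n_enh, 0.5, 5)))
        rk <- callSuperEnhancers(quantifyEnhancers(enh, tr), "top_n",
                                 n = sample(1:5, 1))
        genes <- mkGenes(sample.int(1.3e6, 80), rep(5, 80))
        a <- assignGenes(rk, genes, windowBp = 30000)
        cs <- classGeneSets(a)
        expect_length(intersect(cs$super_genes, cs$typical_genes), 0)
        linked <- unique(as.data.frame(assignmentLinks(a))$gene_id)
        expect_setequal(c(cs$super_genes, cs$typical_genes), linked)
    }
})

test_that("planted super-enhancer target genes are recovered through the window", {
    recalls <- vapply(1:3, function(seed) {
        truth <- generateLandscape(
            syntheticConfig(seed = seed, n_chromosomes = 2L,
                            chrom_length = 4e6, n_typical = 120L,
                            n_super = 8L, n_genes = 200L),
            sequence = FALSE)
        rk <- callSuperEnhancers(
            quantifyEnhancers(truth$constituents, exactTruthTrack(truth)),
            "top_n", n = 8)
        a <- assignGenes(rk, truth$genes, windowBp = 50000)
        planted <- truth$se_target_genes
        mean(planted %in% classGeneSets(a)$super_genes)
    }, numeric(1))
    expect_true(all(recalls >= 0.95))
})
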