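dss <- function(...) DNAStringSet(c(...))

test_that("the scanner finds maximal tandem runs on both strands", {
    out <- scanMicrosatellites(dss(chr1 = "GGAAGGAA"))
    expect_length(out, 1)
    expect_equal(out$repeat_count, 2L)
    expect_equal(out$unit, "GGAA")
    expect_equal(start(out), 1L)

    ## broken second copy: no run
    expect_length(scanMicrosatellites(dss(chr1 = "GGAAGGAT")), 0)

    ## reverse-complement runs are reported as TTCC on the minus strand
    out <- scanMicrosatellites(dss(chr1 = "AATTCCTTCCTTCCAA"))
    expect_equal(out$unit, "TTCC")
    expect_equal(as.character(strand(out)), "-")
    expect_equal(out$repeat_count, 3L)

    ## N splits runs
    out <- scanMicrosatellites(dss(chr1 = "GGAANGGAAGGAA"))
    expect_length(out, 1)
    expect_equal(start(out), 6L)
    expect_equal(out$repeat_count, 2L)

    ## case-insensitive
    out <- scanMicrosatellites(dss(chr1 = "ttggaaggaatt"))
    expect_equal(out$repeat_count, 2L)

    ## minimum repeats respected
    expect_length(scanMicrosatellites(dss(chr1 = "GGAAGGAAGGAA"),
                                      minRepeats = 4L), 0)
    expect_error(scanMicrosatellites(dss(chr1 = "ACGT"), unit = "GGNA"),
                 "ACGT")
    expect_error(scanMicrosatellites(dss(chr1 = "ACGT"), minRepeats = 1),
                 "at least 2")
})

test_that("scanner output equals a regex sliding-window oracle on random sequence", {
    withr::local_seed(79)
    for (rep in 1:60) {
        ## GGAA-enriched alphabet so that runs actually occur
        seqchar <- paste(sample(c("G", "A", "T", "C", "GGAA", "GGAAGGAA"),
                                600, replace = TRUE,
                                prob = c(.24, .24, .24, .24, .03, .01)),
                         collapse = "")
        got <- scanMicrosatellites(dss(chr1 = seqchar))
        want <- bruteMsatScan(seqchar)
        if (is.null(want)) {
            expect_length(got, 0)
            next
        }
        expect_equal(start(got), want$start)
        expect_equal(got$repeat_count, want$repeats)
        expect_equal(got$unit, want$unit)
        ## maximality: extending any run by one unit breaks the pattern
        for (i in seq_along(got)) {
            u <- got$unit[i]
            left <- substr(seqchar, start(got)[i] - 4, start(got)[i] - 1)
            right <- substr(seqchar, end(got)[i] + 1, end(got)[i] + 4)
            if (nchar(left) == 4) expect_false(left == u)
            if (nchar(right) == 4) expect_false(right == u)
        }
    }
})

test_that("region overlap enrichment builds the right table and Fisher test", {
    sup <- GRanges("chr1", IRanges(seq(1, by = 10000, length.out = 6),
                                   width = 5000))
    typ <- GRanges("chr2", IRanges(seq(1, by = 10000, length.out = 6),
                                   width = 5000))
    ## every SUPER contains a feature, no TYPICAL does
    feats <- GRanges("chr1", IRanges(start(sup) + 100, width = 10))
    r <- regionOverlapEnrichment(sup, typ, feats)
    expect_equal(r$table, matrix(c(6, 0, 0, 6), 2, byrow = TRUE,
                                 dimnames = dimnames(r$table)))
    expect_equal(unname(r$result$estimate), Inf)
    ## both extreme tables (a = 6 and a = 0) have point probability
    ## 1/C(12,6), so the two-sided p sums them
    expect_equal(r$result$p.value, 2 / choose(12, 6), tolerance = 1e-12)

    ## no features at all
    r0 <- regionOverlapEnrichment(sup, typ, GRanges())
    expect_equal(r0$table[, 1], c(SUPER = 0, TYPICAL = 0))
    expect_equal(r0$result$p.value, 1.0)
    expect_true(is.nan(unname(r0$result$estimate)))

    ## margins always equal the class sizes
    withr::local_seed(83)
    feats <- GRanges(sample(c("chr1", "chr2"), 30, replace = TRUE),
                     IRanges(sample.int(60000, 30), width = 50))
    r1 <- regionOverlapEnrichment(sup, typ, feats)
    expect_equal(unname(rowSums(r1$table)), c(6, 6))

    expect_error(regionOverlapEnrichment(sup, GRanges(), feats), "non-empty")
    expect_error(regionOverlapEnrichment(sup, sup, feats), "disjoint")
})

test_that("repeat-count comparison partitions by peak overlap", {
    ms <- GRanges("chr1", IRanges(c(100, 2100, 4100, 6100), width = 8),
                  repeat_count = c(8, 7, 2, 3))
    peaks <- GRanges("chr1", IRanges(c(50, 2050), width = 200))
    r <- repeatCountComparison(ms, peaks)
    expect_equal(r$n_in, 2)
    expect_equal(r$n_out, 2)
    expect_equal(r$mean_in, 7.5)
    expect_equal(r$mean_out, 2.5)
    expect_lt(r$p.value, 0.2)

    ## all microsatellites inside peaks: means only, p undefined
    allin <- repeatCountComparison(ms, GRanges("chr1", IRanges(1, 10000)))
    expect_equal(allin$n_out, 0)
    expect_true(is.na(allin$p.value))

    ## identically distributed groups: t = 0, p = 1
    ms2 <- GRanges("chr1", IRanges(c(100, 300, 2100, 2300), width = 8),
                   repeat_count = c(2, 3, 2, 3))
    r2 <- repeatCountComparison(ms2, GRanges("chr1", IRanges(1, 1000)))
    expect_equal(r2$p.value, 1.0)
})
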