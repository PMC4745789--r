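mkTss <- function(pos, chrom = "chr1") {
    GRanges(chrom, IRanges(pos, width = 1),
            gene_id = sprintf("g%03d", seq_along(pos)),
            expression = rep(10, length(pos)))
}

test_that("defineCandidates excludes TSS-proximal and promoter-like peaks", {
    tss <- mkTss(10000)
    ## peak centered exactly on the TSS: removed at exclusion 2500
    atTss <- GRanges("chr1", IRanges(9500, 10500))
    expect_length(defineCandidates(atTss, tss, GRanges()), 0)
    ## peak 100 kb away with no H3K4me3: retained
    far <- GRanges("chr1", IRanges(110000, 111000))
    expect_length(defineCandidates(far, tss, GRanges()), 1)
    ## H3K4me3 covering >= 50% of the peak: removed; < 50%: kept
    k4 <- GRanges("chr1", IRanges(110000, 110600))
    expect_length(defineCandidates(far, tss, k4), 0)
    k4small <- GRanges("chr1", IRanges(110000, 110300))
    expect_length(defineCandidates(far, tss, k4small), 1)
    expect_error(defineCandidates(far, tss, GRanges(), tssExclusionBp = -1),
                 "nonnegative")
    expect_error(defineCandidates(far, tss, GRanges(),
                                  k4me3OverlapFraction = 1.5), "\\[0, 1\\]")
})

test_that("defineCandidates matches an exhaustive pairwise filter oracle", {
    withr::local_seed(41)
    peaks <- randomPeaks(500, max_pos = 2e6, max_width = 4000)
    tss <- mkTss(sample.int(2e6, 80))
    tss <- suppressWarnings(c(tss, mkTss(sample.int(2e6, 20), "chr2")))
    tss$gene_id <- sprintf("g%03d", seq_along(tss))
    k4 <- randomPeaks(120, max_pos = 2e6, max_width = 3000)
    got <- defineCandidates(peaks, tss, k4, 2500, 0.5)
    pc <- as.character(seqnames(peaks)); ps <- start(peaks); pe <- end(peaks)
    tc <- as.character(seqnames(tss)); tp <- start(tss)
    kc <- as.character(seqnames(k4)); ks <- start(k4); ke <- end(k4)
    keep <- vapply(seq_along(peaks), function(i) {
        mid <- (ps[i] + pe[i]) %/% 2
        for (j in seq_along(tp)) {
            if (tc[j] != pc[i]) next
            if (abs(mid - tp[j]) <= 2500) return(FALSE)
        }
        for (j in seq_along(ks)) {
            if (kc[j] != pc[i]) next
            ov <- max(0, min(pe[i], ke[j]) - max(ps[i], ks[j]) + 1)
            if (ov >= 0.5 * (pe[i] - ps[i] + 1)) return(FALSE)
        }
        TRUE
    }, logical(1))
    expect_equal(granges(got), granges(peaks[keep]))
})

test_that("stitching merges transitively within the gap threshold", {
    ## 0-based [0,100) and [200,300): gap 100
    p <- GRanges("chr1", IRanges(c(1, 201), c(100, 300)))
    one <- stitchPeaks(p, 500)
    expect_length(one, 1)
    expect_equal(unlist(range(one))[1], GRanges("chr1", IRanges(1, 300)))
    expect_length(stitchPeaks(p, 50), 2)
    ## gap exactly at the threshold merges; one more base does not
    expect_length(stitchPeaks(p, 100), 1)
    expect_length(stitchPeaks(p, 99), 2)
    expect_error(stitchPeaks(p, -5), "nonnegative")
})

test_that("stitching is idempotent and equals single-linkage clustering", {
    withr::local_seed(43)
    for (rep in 1:20) {
        p <- granges(randomPeaks(60, max_pos = 3e5, max_width = 3000))
        d <- sample(c(0, 100, 5000, 12500), 1)
        st <- stitchPeaks(p, d)
        regions <- unlist(range(st), use.names = FALSE)
        ## idempotence on the stitched regions
        st2 <- stitchPeaks(regions, d)
        expect_equal(granges(unlist(range(st2), use.names = FALSE)),
                     granges(regions))
        ## single-linkage oracle: sort, then cut where gap > d
        ps <- sort(p)
        comp <- integer(length(ps))
        comp[1] <- 1
        cur_end <- end(ps)[1]
        for (i in seq_along(ps)[-1]) {
            gap <- start(ps)[i] - cur_end - 1
            same_chrom <- as.character(seqnames(ps))[i] ==
                as.character(seqnames(ps))[i - 1]
            comp[i] <- comp[i - 1] +
                (!same_chrom || gap > d)
            cur_end <- if (comp[i] == comp[i - 1])
                max(cur_end, end(ps)[i]) else end(ps)[i]
        }
        expect_equal(length(st), max(comp))
    }
})

test_that("quantification ranks enhancers by integrated signal", {
    cov <- GRanges("chr1", IRanges(c(1, 10001), width = 1000),
                   score = c(3, 1))
    tr <- SignalTrack(cov)
    enh <- GRanges("chr1", IRanges(c(1, 10001), width = 1000))
    rk <- quantifyEnhancers(enh, tr)
    gr <- enhancerRegions(rk)
    expect_equal(gr$signal, c(1000, 3000))
    expect_equal(gr$rank, 1:2)
    expect_equal(start(gr), c(10001, 1))
    ## control equal to signal floors everything at zero
    rk0 <- quantifyEnhancers(enh, tr, control = tr)
    expect_equal(enhancerRegions(rk0)$signal, c(0, 0))
})

test_that("ranking equals an independent per-base sum and sort", {
    withr::local_seed(47)
    fx <- randomTrackWithDense(len = 2e5, n_segments = 300)
    s <- seq(1, 190000, by = 950)[1:200]
    enh <- GRanges("chr1", IRanges(s, width = 600))
    rk <- quantifyEnhancers(enh, fx$track)
    want <- vapply(seq_along(enh),
                   function(i) denseRegionSignal(fx$dense, start(enh)[i],
                                                 end(enh)[i]),
                   numeric(1))
    expect_equal(sort(enhancerRegions(rk)$signal), sort(want),
                 tolerance = 1e-9)
    expect_false(is.unsorted(enhancerRegions(rk)$signal))
})

mkRanking <- function(signals) {
    n <- length(signals)
    enh <- GRanges("chr1", IRanges(seq(1, by = 50000, length.out = n),
                                   width = 1000))
    quantifyEnhancers(enh, SignalTrack(GRanges("chr1",
        IRanges(seq(1, by = 50000, length.out = n), width = 1000),
        score = signals / 1000)))
}

test_that("super-enhancer cutoff methods classify the expected suffixes", {
    rk <- callSuperEnhancers(mkRanking(c(1, 1, 1, 100)), "top_n", n = 1)
    gr <- enhancerRegions(rk)
    expect_equal(gr$klass, c("TYPICAL", "TYPICAL", "TYPICAL", "SUPER"))
    expect_equal(gr$signal[gr$klass == "SUPER"], 100)

    ## half_signal: total 34, top {20} carries 20 > 17
    rk <- callSuperEnhancers(mkRanking(c(1, 1, 1, 1, 10, 20)), "half_signal")
    gr <- enhancerRegions(rk)
    expect_equal(sum(gr$klass == "SUPER"), 1)
    expect_equal(gr$signal[gr$klass == "SUPER"], 20)

    expect_error(callSuperEnhancers(mkRanking(c(1, 2)), "top_n", n = 3),
                 "must lie in")
    expect_error(callSuperEnhancers(mkRanking(c(1, 2)), "top_n", n = 0),
                 "must lie in")
    expect_error(callSuperEnhancers(mkRanking(c(1, 2)), "top_n"),
                 "requires n")
})

test_that("tangent cutoff equals a brute-force scan on a hockey stick", {
    withr::local_seed(53)
    for (rep in 1:5) {
        n <- 2000
        body <- sort(runif(n * 0.95, 0, 1000))
        tail_part <- sort(1000 * exp(runif(n * 0.05, 0.5, 5)))
        sig <- sort(c(body, tail_part))
        rk <- callSuperEnhancers(mkRanking(sig), "tangent")
        sig_sorted <- enhancerRegions(rk)$signal
        x <- (seq_along(sig_sorted) - 1) / (length(sig_sorted) - 1)
        y <- sig_sorted / max(sig_sorted)
        brute <- which.min(vapply(seq_along(x), function(i) y[i] - x[i],
                                  numeric(1)))
        expect_equal(rk@cutoffIndex, brute)
        expect_equal(enhancerRegions(rk)$klass,
                     ifelse(sig_sorted > sig_sorted[brute],
                            "SUPER", "TYPICAL"))
    }
})

test_that("SUPER calls always form a suffix of the ascending ranking", {
    withr::local_seed(59)
    for (rep in 1:20) {
        sig <- round(rexp(sample(5:50, 1)) * 100, 1)
        rk <- mkRanking(sig)
        for (m in c("tangent", "half_signal")) {
            kl <- enhancerRegions(callSuperEnhancers(rk, m))$klass
            if (any(kl == "SUPER"))
                expect_true(all(kl[min(which(kl == "SUPER")):length(kl)]
                                == "SUPER"))
        }
        kl <- enhancerRegions(callSuperEnhancers(rk, "top_n",
                                                 n = sample(length(sig), 1)))$klass
        if (any(kl == "SUPER"))
            expect_true(all(kl[min(which(kl == "SUPER")):length(kl)]
                            == "SUPER"))
    }
})

test_that("ranking summaries report signal fractions and class medians", {
    rk <- callSuperEnhancers(mkRanking(c(1, 1, 1, 1)), "top_n", n = 2)
    expect_equal(topSignalFraction(rk, 2), 0.5)
    expect_error(topSignalFraction(rk, 5), "must lie in")

    withr::local_seed(61)
    sig <- sort(round(rexp(500) * 1000, 2))
    rk <- callSuperEnhancers(mkRanking(sig), "half_signal")
    for (k in c(1, 10, 250, 500))
        expect_equal(topSignalFraction(rk, k),
                     sum(sort(sig, decreasing = TRUE)[1:k]) / sum(sig),
                     tolerance = 1e-12)
    s <- summarizeRanking(rk)
    expect_gt(s$super_signal_fraction, 0.5)
    expect_equal(s$n_enhancers, 500)
})

test_that("median enhancer lengths are computed per class", {
    enh <- GRanges("chr1", IRanges(seq(1, by = 50000, length.out = 4),
                                   width = c(10, 20, 30, 5000)))
    tr <- SignalTrack(GRanges("chr1",
        IRanges(seq(1, by = 50000, length.out = 4),
                width = c(10, 20, 30, 5000)),
        score = c(1, 1, 1, 100)))
    rk <- callSuperEnhancers(quantifyEnhancers(enh, tr), "top_n", n = 1)
    s <- summarizeRanking(rk)
    expect_equal(s$median_length_typical, 20)
    expect_equal(s$median_length_super, 5000)
})
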