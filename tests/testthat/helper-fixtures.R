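suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
    library(Biostrings)
})

## constant-density track on one segment
constantTrack <- function(chrom = "chr1", start = 1, end = 1e5, density = 1) {
    SignalTrack(GRanges(chrom, IRanges(start, end), score = density))
}

## random piecewise-constant track on one chromosome together with a dense
## per-base vector oracle (length len)
randomTrackWithDense <- function(len = 10000, n_segments = 50,
                                 chrom = "chr1") {
    bounds <- sort(sample.int(len, 2 * n_segments))
    s <- bounds[seq(1, length(bounds), 2)]
    e <- bounds[seq(2, length(bounds), 2)]
    keep <- s <= e
    s <- s[keep]; e <- e[keep]
    vals <- round(runif(length(s), 0, 5), 3)
    dense <- numeric(len)
    for (i in seq_along(s)) dense[s[i]:e[i]] <- vals[i]
    ## segments may abut but never overlap by construction
    list(track = SignalTrack(GRanges(chrom, IRanges(s, e), score = vals)),
         dense = dense, len = len, chrom = chrom)
}

denseRegionSignal <- function(dense, s, e) {
    s <- max(1, s); e <- min(length(dense), e)
    if (s > e) return(0)
    sum(dense[s:e])
}

## regex-based sliding-window oracle for microsatellite scanning (both
## orientations), independent of the chained matchPattern implementation
bruteMsatScan <- function(seqchar, unit = "GGAA", minRepeats = 2) {
    seqchar <- toupper(seqchar)
    rc <- as.character(reverseComplement(DNAString(unit)))
    one <- function(u) {
        pat <- sprintf("(?:%s){%d,}", u, minRepeats)
        m <- gregexpr(pat, seqchar, perl = TRUE)[[1]]
        if (m[1] == -1) return(NULL)
        data.frame(start = as.integer(m),
                   width = attr(m, "match.length"),
                   unit = u)
    }
    out <- rbind(one(unit), if (rc != unit) one(rc))
    if (is.null(out)) return(out)
    out$repeats <- out$width / nchar(unit)
    out[order(out$start), ]
}

## step-by-step GSEA running-sum oracle (plain loop)
loopEnrichmentScore <- function(metric, hit, weight) {
    N <- length(metric)
    s <- sum(hit)
    sw <- sum(abs(metric[hit])^weight)
    rs <- numeric(N)
    cur <- 0
    for (i in seq_len(N)) {
        if (hit[i]) {
            cur <- cur + (if (sw == 0) 1 / s else abs(metric[i])^weight / sw)
        } else {
            cur <- cur - 1 / (N - s)
        }
        rs[i] <- cur
    }
    rs[which.max(abs(rs))]
}

## exhaustive Mann-Whitney U null by bitmask enumeration (independent of
## the combn-based implementation path)
bitmaskMWPValue <- function(x, y, alternative = "two.sided") {
    pooled <- c(x, y)
    n <- length(pooled); nx <- length(x)
    uFor <- function(xs, ys)
        sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    u_obs <- uFor(x, y)
    us <- c()
    for (mask in 0:(2^n - 1)) {
        idx <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1) == 1)
        if (length(idx) != nx) next
        us <- c(us, uFor(pooled[idx], pooled[-idx]))
    }
    m <- length(us)
    switch(alternative,
           greater = sum(us >= u_obs) / m,
           less = sum(us <= u_obs) / m,
           two.sided = min(1, 2 * min(sum(us <= u_obs), sum(us >= u_obs)) / m))
}

## small, fast generator configuration for unit tests
smallConfig <- function(seed = 1, ...) {
    syntheticConfig(seed = seed,
                    n_chromosomes = 2L, chrom_length = 1.5e6,
                    n_typical = 40L, n_super = 4L,
                    n_genes = 80L, n_screen_genes = 60L,
                    n_lines = 12L, n_target_lines = 4L, ...)
}

## exact (noise-free) signal track from planted truth: density = strength
## over constituents, zero background
exactTruthTrack <- function(truth) {
    const <- unlist(truth$constituents, use.names = FALSE)
    strength <- rep(truth$enhancers$strength, lengths(truth$constituents))
    SignalTrack(GRanges(seqnames(const), ranges(const), score = strength))
}

## random BED-like peak GRanges
randomPeaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                        max_width = 5000) {
    s <- sample.int(max_pos, n, replace = TRUE)
    w <- sample.int(max_width, n, replace = TRUE)
    GRanges(sample(chroms, n, replace = TRUE), IRanges(s, width = w),
            name = sprintf("pk%04d", seq_len(n)),
            score = round(runif(n, 0, 100), 2))
}
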