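## Interval arithmetic on top of GenomicRanges: signal integration over
## regions and pairwise overlap/gap relations.

## muffle only GenomeInfoDb's "no sequence levels in common" warning, which
## is expected whenever two legitimate range sets live on different
## chromosomes
.quietSeqlevels <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
        if (grepl("no sequence levels in common", conditionMessage(w)))
            invokeRestart("muffleWarning")
    })
}

#' Integrate signal density over regions
#'
#' Integrates a [SignalTrack-class] density over each query region:
#' \eqn{\sum} over covered sub-segments of (density x overlap length), i.e.
#' total RPM in the region. Additive over a partition of the region.
#' Chromosomes absent from the track contribute 0 (with a warning).
#'
#' @param track A [SignalTrack-class].
#' @param regions A [GenomicRanges::GRanges] of query regions.
#' @return A numeric vector of signals (RPM), parallel to `regions`.
#' @examples
#' tr <- SignalTrack(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(1, 100), score = 2))
#' regionSignal(tr, GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20)))
#' @export
regionSignal <- function(track, regions) {
    stopifnot(is(track, "SignalTrack"), is(regions, "GRanges"))
    cov <- trackCoverage(track)
    out <- numeric(length(regions))
    if (!length(regions) || !length(cov)) return(out)
    missing_chr <- setdiff(unique(as.character(seqnames(regions))),
                           unique(as.character(seqnames(cov))))
    if (length(missing_chr))
        warning("no signal coverage for chromosome(s): ",
                paste(missing_chr, collapse = ", "),
                "; reporting 0 signal there")
    hits <- .quietSeqlevels(findOverlaps(regions, cov, ignore.strand = TRUE))
    if (!length(hits)) return(out)
    q <- queryHits(hits); s <- subjectHits(hits)
    ovw <- pmin(end(regions)[q], end(cov)[s]) -
           pmax(start(regions)[q], start(cov)[s]) + 1
    contrib <- as.numeric(ovw) * cov$score[s]
    agg <- tapply(contrib, q, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
}

#' Pairwise overlap length and gap distance between intervals
#'
#' For parallel interval vectors `a` and `b`: overlap is the number of
#' shared bases; distance is 0 when the intervals overlap or abut and the
#' length of the gap between them otherwise. Intervals on different
#' chromosomes have overlap 0 and distance `Inf`. Symmetric in `a`, `b`.
#'
#' @param a,b [GenomicRanges::GRanges] of equal length (or length 1,
#'   recycled). Strand is ignored.
#' @return A data.frame with integer column `overlap` and numeric column
#'   `distance`.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(61, 70))
#' intervalRelate(a, b)  # overlap 0, distance 50
#' @export
intervalRelate <- function(a, b) {
    stopifnot(is(a, "GRanges"), is(b, "GRanges"))
    n <- max(length(a), length(b))
    if (length(a) == 1L) a <- rep(a, n)
    if (length(b) == 1L) b <- rep(b, n)
    stopifnot(length(a) == length(b))
    same <- as.character(seqnames(a)) == as.character(seqnames(b))
    ov <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
    gap <- pmax(0L, pmax(start(a), start(b)) - pmin(end(a), end(b)) - 1L)
    ov[!same] <- 0L
    dist <- as.numeric(gap)
    dist[ov > 0L] <- 0
    dist[!same] <- Inf
    data.frame(overlap = ov, distance = dist)
}
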