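## Enhancer definition and super-enhancer calling: TSS/H3K4me3 exclusion,
## ROSE-style stitching, signal quantification, and rank-cutoff
## classification of the hockey-stick curve.

#' Define distal enhancer candidates from H3K27Ac peaks
#'
#' Keeps H3K27Ac peaks that are distal to every TSS and not promoter-like:
#' the peak midpoint must lie more than `tssExclusionBp` from every TSS, and
#' the peak's overlap with any single H3K4me3 peak must be less than
#' `k4me3OverlapFraction` of the H3K27Ac peak length. The midpoint (not
#' any-overlap) rule keeps broad shoulder peaks that merely graze a TSS
#' window, judging them by their center.
#'
#' @param k27acPeaks H3K27Ac peaks ([GenomicRanges::GRanges]).
#' @param genes Gene TSS positions (width-1 GRanges, e.g. from
#'   [readGeneTable()]).
#' @param k4me3Peaks H3K4me3 peaks (GRanges).
#' @param tssExclusionBp Minimum midpoint-to-TSS distance in bp
#'   (default 2500).
#' @param k4me3OverlapFraction Fraction of the H3K27Ac peak length in
#'   `[0, 1]`; overlap with any H3K4me3 peak at or above this fraction
#'   excludes the peak (default 0.5).
#' @return The retained subset of `k27acPeaks`.
#' @export
defineCandidates <- function(k27acPeaks, genes, k4me3Peaks,
                             tssExclusionBp = 2500,
                             k4me3OverlapFraction = 0.5) {
    stopifnot(is(k27acPeaks, "GRanges"), is(genes, "GRanges"),
              is(k4me3Peaks, "GRanges"))
    if (tssExclusionBp < 0)
        stop("tssExclusionBp must be nonnegative")
    if (k4me3OverlapFraction < 0 || k4me3OverlapFraction > 1)
        stop("k4me3OverlapFraction must lie in [0, 1]")
    if (!length(k27acPeaks)) return(k27acPeaks)
    keep <- rep(TRUE, length(k27acPeaks))
    ## midpoint within the exclusion radius of any TSS?
    mid <- (start(k27acPeaks) + end(k27acPeaks)) %/% 2L
    midpoints <- GRanges(seqnames(k27acPeaks), IRanges(mid, width = 1L))
    if (length(genes)) {
        tss_windows <- suppressWarnings(
            trim(resize(granges(genes), width = 2 * tssExclusionBp + 1,
                        fix = "center")))
        keep[overlapsAny(midpoints, tss_windows, ignore.strand = TRUE)] <- FALSE
    }
    ## promoter-like: large overlap with a single H3K4me3 peak
    if (length(k4me3Peaks)) {
        hits <- findOverlaps(k27acPeaks, k4me3Peaks, ignore.strand = TRUE)
        if (length(hits)) {
            q <- queryHits(hits); s <- subjectHits(hits)
            ovw <- pmin(end(k27acPeaks)[q], end(k4me3Peaks)[s]) -
                   pmax(start(k27acPeaks)[q], start(k4me3Peaks)[s]) + 1L
            frac <- ovw / width(k27acPeaks)[q]
            keep[unique(q[frac >= k4me3OverlapFraction])] <- FALSE
        }
    }
    k27acPeaks[keep]
}

#' Stitch nearby peaks into enhancers
#'
#' Transitively merges peaks whose gap is at most `stitchDistanceBp` into
#' one enhancer (single-linkage on genomic distance). The returned
#' enhancers are disjoint and separated by more than `stitchDistanceBp`.
#'
#' @param peaks A [GenomicRanges::GRanges] of (candidate) peaks.
#' @param stitchDistanceBp Maximum gap in bp to merge across
#'   (default 12500, the ROSE convention).
#' @return A [GenomicRanges::GRangesList]: one element per enhancer holding
#'   its constituent peaks; the enhancer region is the range of each
#'   element.
#' @examples
#' p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)))
#' length(stitchPeaks(p, 500))  # 1
#' length(stitchPeaks(p, 50))   # 2
#' @export
stitchPeaks <- function(peaks, stitchDistanceBp = 12500) {
    stopifnot(is(peaks, "GRanges"))
    if (stitchDistanceBp < 0)
        stop("stitchDistanceBp must be nonnegative")
    peaks <- sort(peaks, ignore.strand = TRUE)
    strand(peaks) <- "*"
    if (!length(peaks))
        return(GRangesList())
    merged <- reduce(peaks, min.gapwidth = stitchDistanceBp + 1,
                     with.revmap = TRUE, ignore.strand = TRUE)
    grl <- relist(peaks[unlist(merged$revmap)], merged$revmap)
    names(grl) <- NULL
    grl
}

#' Quantify stitched enhancers and rank by signal
#'
#' Computes each enhancer's H3K27Ac signal with [regionSignal()] (minus the
#' control signal, floored at 0, when a control track is supplied) and
#' returns the enhancers sorted by ascending signal, ties broken by genomic
#' position for determinism. Classification is left unset; see
#' [callSuperEnhancers()].
#'
#' @param enhancers A [GenomicRanges::GRangesList] from [stitchPeaks()], or
#'   a plain disjoint [GenomicRanges::GRanges] of enhancer regions.
#' @param track H3K27Ac [SignalTrack-class].
#' @param control Optional input-control [SignalTrack-class] to subtract.
#' @return An [EnhancerRanking-class] with `klass` unset.
#' @export
quantifyEnhancers <- function(enhancers, track, control = NULL) {
    if (is(enhancers, "GRanges")) {
        grl <- as(granges(enhancers), "GRangesList")
    } else {
        stopifnot(is(enhancers, "GRangesList"))
        grl <- enhancers
    }
    regions <- unlist(range(grl), use.names = FALSE)
    if (!isDisjoint(regions))
        stop("enhancer regions must be disjoint")
    ## stable ids by genomic position
    pos_order <- order(as.character(seqnames(regions)), start(regions),
                       end(regions))
    ids <- character(length(regions))
    ids[pos_order] <- sprintf("enh_%05d", seq_along(regions))
    sig <- regionSignal(track, regions)
    if (!is.null(control)) {
        stopifnot(is(control, "SignalTrack"))
        sig <- pmax(0, sig - regionSignal(control, regions))
    }
    o <- order(sig, as.character(seqnames(regions)), start(regions))
    regions <- regions[o]
    grl <- grl[o]
    mcols(regions) <- DataFrame(
        enhancer_id = ids[o],
        signal = sig[o],
        rank = seq_along(o),
        n_constituents = lengths(grl),
        klass = rep(NA_character_, length(o)))
    new("EnhancerRanking",
        enhancers = regions,
        constituents = grl,
        cutoffSignal = NA_real_,
        cutoffIndex = NA_integer_,
        totalSignal = sum(sig),
        method = NA_character_)
}

#' Classify super-enhancers on the ranked signal curve
#'
#' Assigns `klass` and the cutoff on an [EnhancerRanking-class]:
#' \describe{
#'   \item{`tangent`}{Scale ascending rank index to `x` in `[0, 1]` and
#'     signal to `y` in `[0, 1]` (divide by the maximum); the cutoff index
#'     minimizes `y - x` (the point furthest below the diagonal, where the
#'     hockey-stick inflects); SUPER are enhancers with signal strictly
#'     above the cutoff signal.}
#'   \item{`top_n`}{SUPER are the `n` highest-signal enhancers.}
#'   \item{`half_signal`}{SUPER is the smallest top-ranked set whose summed
#'     signal first exceeds half the total signal.}
#' }
#' Under every method the SUPER set is a suffix of the ascending ranking.
#'
#' @param ranking An [EnhancerRanking-class] from [quantifyEnhancers()].
#' @param method `"tangent"` (default), `"top_n"` or `"half_signal"`.
#' @param n Number of super-enhancers; required iff `method = "top_n"`.
#' @return The ranking with `klass`, `cutoffSignal`, `cutoffIndex` and
#'   `method` filled in.
#' @export
callSuperEnhancers <- function(ranking,
                               method = c("tangent", "top_n", "half_signal"),
                               n = NULL) {
    stopifnot(is(ranking, "EnhancerRanking"))
    method <- match.arg(method)
    gr <- ranking@enhancers
    ne <- length(gr)
    if (!ne) stop("ranking is empty")
    sig <- gr$signal
    if (method == "top_n") {
        if (is.null(n)) stop("method 'top_n' requires n")
        if (n <= 0 || n > ne)
            stop("n must lie in [1, ", ne, "]")
        cutoff_index <- ne - as.integer(n)
        super <- seq_len(ne) > cutoff_index
    } else if (method == "half_signal") {
        total <- sum(sig)
        cum_from_top <- cumsum(rev(sig))
        k <- which(cum_from_top > total / 2)[1L]
        if (is.na(k)) k <- ne   # all-zero signal landscape
        cutoff_index <- ne - k
        super <- seq_len(ne) > cutoff_index
    } else {
        if (max(sig) == 0) {
            cutoff_index <- ne
            super <- rep(FALSE, ne)
        } else {
            x <- if (ne == 1L) 0 else (seq_len(ne) - 1) / (ne - 1)
            y <- sig / max(sig)
            cutoff_index <- which.min(y - x)
            super <- sig > sig[cutoff_index]
        }
    }
    gr$klass <- ifelse(super, "SUPER", "TYPICAL")
    cutoff_signal <- if (cutoff_index >= 1L && cutoff_index <= ne)
        sig[cutoff_index] else 0
    initialize(ranking,
               enhancers = gr,
               cutoffSignal = cutoff_signal,
               cutoffIndex = as.integer(cutoff_index),
               method = method)
}

#' Fraction of total signal carried by the top-k enhancers
#'
#' @param ranking An [EnhancerRanking-class].
#' @param k Number of top (highest-signal) enhancers, in `[1, n]`.
#' @return `sum(signal of top k) / totalSignal`.
#' @export
topSignalFraction <- function(ranking, k) {
    stopifnot(is(ranking, "EnhancerRanking"))
    ne <- length(ranking@enhancers)
    if (k < 1 || k > ne) stop("k must lie in [1, ", ne, "]")
    sig <- ranking@enhancers$signal
    sum(tail(sig, k)) / ranking@totalSignal
}

#' Summarize an enhancer ranking
#'
#' @param ranking A classified [EnhancerRanking-class].
#' @return A list with `n_enhancers`, `n_super`, `super_signal_fraction`
#'   (signal fraction on the SUPER set), and the median region lengths of
#'   each class (`median_length_typical`, `median_length_super`).
#' @export
summarizeRanking <- function(ranking) {
    stopifnot(is(ranking, "EnhancerRanking"))
    gr <- ranking@enhancers
    if (all(is.na(gr$klass)))
        stop("classify the ranking with callSuperEnhancers() first")
    super <- gr$klass == "SUPER"
    list(
        n_enhancers = length(gr),
        n_super = sum(super),
        super_signal_fraction =
            if (any(super)) topSignalFraction(ranking, sum(super)) else 0,
        median_length_typical =
            if (any(!super)) median(width(gr)[!super]) else NA_real_,
        median_length_super =
            if (any(super)) median(width(gr)[super]) else NA_real_)
}
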