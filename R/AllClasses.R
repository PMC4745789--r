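## Central S4 containers. All genomic coordinates inside the package are
## GRanges (1-based, closed); BED/bedGraph 0-based half-open conventions are
## converted at the IO boundary.

#' SignalTrack: library-normalized per-base signal density
#'
#' A piecewise-constant signal density (reads per million per base) over a
#' genome, stored as a sorted, disjoint \linkS4class{GRanges} with a numeric
#' `score` column. Positions not covered by any range have density zero.
#'
#' @slot cov A sorted, disjoint [GenomicRanges::GRanges] whose `score`
#'   metadata column holds nonnegative RPM-per-base densities.
#' @seealso [readSignalTrack()], [regionSignal()], [buildMetagene()]
#' @export
setClass("SignalTrack", slots = c(cov = "GRanges"))

setValidity("SignalTrack", function(object) {
    gr <- object@cov
    msg <- character()
    if (is.null(gr$score) || !is.numeric(gr$score))
        msg <- c(msg, "coverage ranges must carry a numeric 'score' column")
    else if (any(gr$score < 0))
        msg <- c(msg, "signal densities must be nonnegative")
    if (length(gr) && !isDisjoint(gr))
        msg <- c(msg, "coverage ranges must be non-overlapping")
    if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack from a GRanges of constant-density segments
#'
#' @param cov A [GenomicRanges::GRanges] with a nonnegative numeric `score`
#'   column giving RPM-per-base density on each (non-overlapping) segment.
#'   Segments are sorted; zero-density segments are dropped.
#' @return A [SignalTrack-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), score = 2)
#' SignalTrack(gr)
#' @export
SignalTrack <- function(cov = GRanges(score = numeric())) {
    if (is.null(cov$score)) cov$score <- numeric(length(cov))
    cov <- sort(cov[cov$score != 0])
    new("SignalTrack", cov = cov)
}

#' @describeIn SignalTrack-class The underlying coverage GRanges.
#' @param x A `SignalTrack`.
#' @export
trackCoverage <- function(x) {
    stopifnot(is(x, "SignalTrack"))
    x@cov
}

setMethod("show", "SignalTrack", function(object) {
    gr <- object@cov
    tot <- sum(as.numeric(width(gr)) * gr$score)
    cat("SignalTrack with ", length(gr), " segments on ",
        length(unique(as.character(seqnames(gr)))), " sequence(s); ",
        "total signal ", format(tot, digits = 6), " RPM\n", sep = "")
})

#' EnhancerRanking: stitched enhancers ranked by signal
#'
#' Enhancers (stitched H3K27Ac peak clusters) sorted by ascending signal,
#' with the super/typical classification and the rank cutoff that produced
#' it. Rank 1 is the lowest-signal enhancer.
#'
#' @slot enhancers A [GenomicRanges::GRanges], sorted by ascending signal,
#'   with metadata columns `enhancer_id`, `signal`, `rank`, `n_constituents`
#'   and `klass` (`"TYPICAL"`/`"SUPER"`, `NA` before [callSuperEnhancers()]).
#' @slot constituents A [GenomicRanges::GRangesList] of the constituent
#'   peaks of each enhancer, parallel to `enhancers`.
#' @slot cutoffSignal,cutoffIndex Signal value and ascending-rank index of
#'   the classification cutoff (`NA` before classification). Enhancers with
#'   `signal > cutoffSignal` are SUPER.
#' @slot totalSignal Sum of all enhancer signals (RPM).
#' @slot method Cutoff method used (`"tangent"`, `"top_n"`, `"half_signal"`,
#'   or `NA`).
#' @seealso [stitchPeaks()], [quantifyEnhancers()], [callSuperEnhancers()]
#' @export
setClass("EnhancerRanking", slots = c(
    enhancers    = "GRanges",
    constituents = "GRangesList",
    cutoffSignal = "numeric",
    cutoffIndex  = "integer",
    totalSignal  = "numeric",
    method       = "character"
))

setValidity("EnhancerRanking", function(object) {
    gr <- object@enhancers
    msg <- character()
    need <- c("enhancer_id", "signal", "rank", "klass")
    if (!all(need %in% names(mcols(gr))))
        return(paste("enhancers must carry metadata columns:",
                     paste(need, collapse = ", ")))
    if (length(gr)) {
        if (is.unsorted(gr$signal))
            msg <- c(msg, "enhancers must be sorted by ascending signal")
        if (!identical(as.integer(gr$rank), seq_along(gr)))
            msg <- c(msg, "ranks must be 1..n in ascending-signal order")
        if (any(gr$signal < 0)) msg <- c(msg, "signals must be nonnegative")
        kl <- gr$klass
        if (!all(is.na(kl) | kl %in% c("TYPICAL", "SUPER")))
            msg <- c(msg, "klass must be TYPICAL, SUPER or NA")
        if (any(kl %in% "SUPER")) {
            ## SUPER must be a suffix of the ascending ranking
            first_super <- min(which(kl == "SUPER"))
            if (any(kl[first_super:length(kl)] != "SUPER"))
                msg <- c(msg, "SUPER enhancers must form a suffix of the ranking")
        }
        if (length(object@constituents) != length(gr))
            msg <- c(msg, "constituents must be parallel to enhancers")
        if (!isTRUE(all.equal(object@totalSignal, sum(gr$signal))))
            msg <- c(msg, "totalSignal must equal the sum of enhancer signals")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "EnhancerRanking", function(object) {
    gr <- object@enhancers
    ns <- sum(gr$klass %in% "SUPER")
    cat("EnhancerRanking with ", length(gr), " enhancers",
        if (!is.na(object@method))
            paste0(" (", ns, " SUPER, method '", object@method, "')"),
        "\n  total signal: ", format(object@totalSignal, digits = 6), " RPM\n",
        sep = "")
    if (!is.na(object@cutoffIndex))
        cat("  cutoff: rank ", object@cutoffIndex, ", signal ",
            format(object@cutoffSignal, digits = 6), "\n", sep = "")
})

#' @describeIn EnhancerRanking-class The ranked enhancer GRanges
#'   (ascending signal).
#' @param x An `EnhancerRanking`.
#' @export
enhancerRegions <- function(x) {
    stopifnot(is(x, "EnhancerRanking"))
    x@enhancers
}

#' @describeIn EnhancerRanking-class Constituent peaks per enhancer.
#' @export
enhancerConstituents <- function(x) {
    stopifnot(is(x, "EnhancerRanking"))
    x@constituents
}

#' @describeIn EnhancerRanking-class Enhancers classified SUPER.
#' @export
superEnhancers <- function(x) {
    gr <- enhancerRegions(x)
    gr[gr$klass %in% "SUPER"]
}

#' @describeIn EnhancerRanking-class Enhancers classified TYPICAL.
#' @export
typicalEnhancers <- function(x) {
    gr <- enhancerRegions(x)
    gr[gr$klass %in% "TYPICAL"]
}

#' GeneAssignment: enhancer-to-gene links within a distance window
#'
#' Links between enhancers and transcriptionally active genes whose TSS lies
#' within a window of the enhancer boundary, plus the resulting disjoint
#' SUPER-associated / TYPICAL-associated gene sets (a gene linked to both
#' classes counts as SUPER-associated).
#'
#' @slot links A [S4Vectors::DataFrame] with columns `enhancer_id`,
#'   `gene_id`, `distance` (bp gap, 0 if the TSS is inside the enhancer) and
#'   `klass` of the linked enhancer.
#' @slot superGenes,typicalGenes Disjoint character vectors of gene ids.
#' @slot window,expressionThreshold Parameters the assignment was built with.
#' @seealso [assignGenes()], [classGeneSets()]
#' @export
setClass("GeneAssignment", slots = c(
    links               = "DataFrame",
    superGenes          = "character",
    typicalGenes        = "character",
    window              = "numeric",
    expressionThreshold = "numeric"
))

setValidity("GeneAssignment", function(object) {
    msg <- character()
    need <- c("enhancer_id", "gene_id", "distance", "klass")
    if (!all(need %in% colnames(object@links)))
        return(paste("links must have columns:", paste(need, collapse = ", ")))
    if (length(intersect(object@superGenes, object@typicalGenes)))
        msg <- c(msg, "superGenes and typicalGenes must be disjoint")
    if (nrow(object@links) && any(object@links$distance > object@window))
        msg <- c(msg, "all link distances must be <= window")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GeneAssignment", function(object) {
    cat("GeneAssignment: ", nrow(object@links), " links within ",
        object@window, " bp\n  ", length(object@superGenes),
        " SUPER-associated genes, ", length(object@typicalGenes),
        " TYPICAL-associated genes (expression >= ",
        object@expressionThreshold, ")\n", sep = "")
})

#' @describeIn GeneAssignment-class The link table.
#' @param x A `GeneAssignment`.
#' @export
assignmentLinks <- function(x) {
    stopifnot(is(x, "GeneAssignment"))
    x@links
}
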