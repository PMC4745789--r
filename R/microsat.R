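## GGAA microsatellite scanning and the enrichment statistics of the
## super-enhancer analysis: region-overlap Fisher tests and the repeat-count
## comparison inside vs outside EWS/FLI1 peaks.

## maximal tandem runs of `unit` in one sequence; returns start/repeat pairs
.scanUnitRuns <- function(seq, unit, minRepeats) {
    ulen <- nchar(unit)
    hits <- start(matchPattern(DNAString(unit), seq, fixed = TRUE))
    if (!length(hits))
        return(data.frame(start = integer(), repeats = integer()))
    is_hit <- logical(length(seq))
    is_hit[hits] <- TRUE
    starts <- integer(); reps <- integer()
    i <- 1L
    nh <- length(hits)
    while (i <= nh) {
        s <- hits[i]
        r <- 1L
        while (s + r * ulen <= length(seq) && is_hit[s + r * ulen])
            r <- r + 1L
        if (r >= minRepeats) {
            starts <- c(starts, s)
            reps <- c(reps, r)
            run_end <- s + r * ulen - 1L
            while (i <= nh && hits[i] <= run_end) i <- i + 1L
        } else {
            i <- i + 1L
        }
    }
    data.frame(start = starts, repeats = reps)
}

#' Scan a genome for tandem microsatellite runs
#'
#' Finds all maximal, exact, non-overlapping tandem runs of at least
#' `minRepeats` copies of a 4-base unit (default GGAA) on the forward
#' strand, plus runs of the reverse complement (reported with the
#' complement unit, e.g. TTCC, on the minus strand). Runs are maximal: no
#' reported run extends by one more unit copy on either side. Scanning is
#' case-insensitive and runs containing N are split at the N (an N never
#' matches).
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param unit The repeat unit, a 4-base ACGT string (default `"GGAA"`).
#' @param minRepeats Minimum number of tandem copies (default 2).
#' @return A [GenomicRanges::GRanges] with metadata columns `unit` and
#'   `repeat_count`; each range has width `4 * repeat_count`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(chr1 = "TTGGAAGGAATT"))
#' scanMicrosatellites(seqs)
#' @export
scanMicrosatellites <- function(genome, unit = "GGAA", minRepeats = 2L) {
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- readGenome(genome)
    stopifnot(is(genome, "DNAStringSet"))
    unit <- toupper(unit)
    if (nchar(unit) != 4L || grepl("[^ACGT]", unit))
        stop("unit must be a 4-base ACGT string")
    if (minRepeats < 2L) stop("minRepeats must be at least 2")
    rc_unit <- as.character(reverseComplement(DNAString(unit)))
    out <- list()
    for (chrom in names(genome)) {
        seq <- genome[[chrom]]
        for (u in unique(c(unit, rc_unit))) {
            runs <- .scanUnitRuns(seq, u, minRepeats)
            if (nrow(runs))
                out[[length(out) + 1L]] <- data.frame(
                    chrom = chrom, start = runs$start,
                    repeats = runs$repeats,
                    strand = if (u == unit) "+" else "-",
                    unit = u)
        }
    }
    if (!length(out)) {
        gr <- GRanges()
        gr$unit <- character()
        gr$repeat_count <- integer()
        return(gr)
    }
    df <- do.call(rbind, out)
    gr <- GRanges(df$chrom, IRanges(df$start, width = 4L * df$repeats),
                  strand = df$strand, unit = df$unit,
                  repeat_count = df$repeats)
    sort(gr, ignore.strand = TRUE)
}

#' Fisher enrichment of a feature in SUPER vs TYPICAL regions
#'
#' Builds the 2x2 table (rows: SUPER/TYPICAL region class; columns: region
#' contains at least one feature / contains none; overlap of any length
#' counts) and applies [fisherExact()]. This is the test behind the
#' EWS/FLI1-peak and GGAA-microsatellite enrichment at super-enhancers.
#'
#' @param superRegions,typicalRegions Disjoint region classes
#'   ([GenomicRanges::GRanges]), both non-empty.
#' @param features Feature intervals (GRanges), e.g. EWS/FLI1 peaks or
#'   microsatellites.
#' @return A list with `table` (2x2 matrix: rows SUPER/TYPICAL, columns
#'   with/without feature) and `result` (the [fisherExact()] `"htest"`).
#' @export
regionOverlapEnrichment <- function(superRegions, typicalRegions, features) {
    stopifnot(is(superRegions, "GRanges"), is(typicalRegions, "GRanges"),
              is(features, "GRanges"))
    if (!length(superRegions) || !length(typicalRegions))
        stop("both region classes must be non-empty")
    if (length(.quietSeqlevels(findOverlaps(superRegions, typicalRegions,
                                            ignore.strand = TRUE))))
        stop("region classes must be disjoint")
    a <- sum(.quietSeqlevels(
        overlapsAny(superRegions, features, ignore.strand = TRUE)))
    cc <- sum(.quietSeqlevels(
        overlapsAny(typicalRegions, features, ignore.strand = TRUE)))
    tab <- matrix(c(a, length(superRegions) - a,
                    cc, length(typicalRegions) - cc),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("SUPER", "TYPICAL"),
                                  c("with_feature", "without_feature")))
    list(table = tab, result = fisherExact(tab))
}

#' Compare microsatellite repeat counts inside vs outside binding peaks
#'
#' Partitions microsatellites by overlap (any shared base) with the peak
#' set and compares repeat counts between the two groups with [welchT()]
#' (two-sided). With fewer than 2 members in a group only the group means
#' are reported and the p-value is `NA`.
#'
#' @param microsatellites Microsatellite [GenomicRanges::GRanges] with a
#'   `repeat_count` column (see [scanMicrosatellites()]).
#' @param peaks Binding peaks (GRanges), e.g. EWS/FLI1 ChIP-seq peaks.
#' @return A list with `n_in`, `n_out`, `mean_in`, `mean_out`, `p.value`
#'   and `test` (the [welchT()] `"htest"`, or `NULL` when degenerate).
#' @export
repeatCountComparison <- function(microsatellites, peaks) {
    stopifnot(is(microsatellites, "GRanges"), is(peaks, "GRanges"))
    if (!length(microsatellites) || !length(peaks))
        stop("both inputs must be non-empty")
    if (is.null(microsatellites$repeat_count))
        stop("microsatellites must carry a repeat_count column")
    inside <- .quietSeqlevels(
        overlapsAny(microsatellites, peaks, ignore.strand = TRUE))
    x <- microsatellites$repeat_count[inside]
    y <- microsatellites$repeat_count[!inside]
    res <- list(n_in = length(x), n_out = length(y),
                mean_in = if (length(x)) mean(x) else NA_real_,
                mean_out = if (length(y)) mean(y) else NA_real_,
                p.value = NA_real_, test = NULL)
    if (length(x) >= 2L && length(y) >= 2L &&
        (stats::var(x) > 0 || stats::var(y) > 0)) {
        tt <- welchT(x, y)
        res$p.value <- tt$p.value
        res$test <- tt
    }
    res
}
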