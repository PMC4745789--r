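## Readers/writers for the plain-text formats the pipeline consumes:
## BED peak files, bedGraph signal tracks, gene tables, screen tables, GMT
## gene sets. BED and bedGraph are 0-based half-open on disk and become
## 1-based closed GRanges in memory.

#' Read a BED peak file into a GRanges
#'
#' Reads BED3/BED5/BED6 (tab-separated, no header). The score is taken from
#' column 5 when present, else 0; the name from column 4 when present. An
#' optional `summit_offset` numeric column 7 (0-based offset from the peak
#' start) is carried through when present. Records are returned sorted by
#' (chrom, start, end).
#'
#' @param path Path to a BED file. An empty file yields an empty GRanges.
#' @param expectedColumns Minimum number of tab-separated fields each record
#'   must have (default 3).
#' @return A sorted [GenomicRanges::GRanges] with metadata columns `name`,
#'   `score` and (when present) `summit_offset`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tpk\t7.5", f)
#' readPeaks(f)
#' @export
readPeaks <- function(path, expectedColumns = 3L) {
    stopifnot(file.exists(path), expectedColumns >= 3L)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        gr <- GRanges()
        gr$name <- character()
        gr$score <- numeric()
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < expectedColumns))
        stop("BED record with fewer than ", expectedColumns,
             " fields at line ", which(nf < expectedColumns)[1L])
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
    if (length(bad))
        stop("non-integer BED coordinates at line ", bad[1L])
    bad <- which(start0 >= end0 | start0 < 0)
    if (length(bad))
        stop("invalid BED interval (start >= end or negative) at line ", bad[1L])
    name <- if (max(nf) >= 4L)
        vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", "")
    else rep("", length(fields))
    score <- if (max(nf) >= 5L) {
        s <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", "")
        suppressWarnings(as.numeric(s))
    } else rep(0, length(fields))
    score[is.na(score)] <- 0
    strand <- if (max(nf) >= 6L)
        vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", "")
    else rep("*", length(fields))
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                  name = name, score = score)
    if (max(nf) >= 7L) {
        so <- suppressWarnings(as.numeric(
            vapply(fields, function(f) if (length(f) >= 7L) f[[7L]] else NA_character_, "")))
        if (any(!is.na(so) & (so < 0 | so >= width(gr))))
            stop("summit offset outside peak at line ",
                 which(!is.na(so) & (so < 0 | so >= width(gr)))[1L])
        gr$summit_offset <- so
    }
    gr <- GenomeInfoDb::sortSeqlevels(gr)
    sort(gr, ignore.strand = TRUE)
}

#' Write peaks to a BED file
#'
#' Inverse of [readPeaks()]: writes BED with name and score columns (plus
#' strand and any extra metadata columns requested), converting back to
#' 0-based half-open coordinates.
#'
#' @param peaks A [GenomicRanges::GRanges]; metadata columns `name` and
#'   `score` are used when present.
#' @param path Output file path.
#' @param extraColumns Character vector of additional metadata column names
#'   to append after the strand field.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path, extraColumns = character()) {
    df <- data.frame(
        chrom = as.character(seqnames(peaks)),
        start = start(peaks) - 1L,
        end = end(peaks),
        name = if (!is.null(peaks$name)) peaks$name else ".",
        score = if (!is.null(peaks$score)) peaks$score else 0,
        strand = {
            s <- as.character(strand(peaks))
            s[s == "*"] <- "."
            s
        },
        stringsAsFactors = FALSE)
    for (col in extraColumns)
        df[[col]] <- as.vector(mcols(peaks)[[col]])
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a bedGraph signal track
#'
#' Reads a 4-column bedGraph into a [SignalTrack-class]. Intervals within a
#' chromosome must be non-overlapping; the first offending pair is named
#' otherwise. Uncovered positions have density 0.
#'
#' @param path Path to a bedGraph file. An empty file yields a track that is
#'   zero everywhere.
#' @return A [SignalTrack-class].
#' @export
readSignalTrack <- function(path) {
    stopifnot(file.exists(path))
    if (file.size(path) == 0 ||
        !length(readLines(path, n = 1L)))
        return(SignalTrack())
    gr <- rtracklayer::import(path, format = "bedGraph")
    strand(gr) <- "*"
    gr <- sort(gr)
    if (length(gr) > 1L) {
        ov <- which(start(gr)[-1L] <= end(gr)[-length(gr)] &
                    as.character(seqnames(gr))[-1L] ==
                    as.character(seqnames(gr))[-length(gr)])
        if (length(ov)) {
            i <- ov[1L]
            stop("overlapping bedGraph intervals: ",
                 seqnames(gr)[i], ":", start(gr)[i] - 1L, "-", end(gr)[i],
                 " and ", seqnames(gr)[i + 1L], ":", start(gr)[i + 1L] - 1L,
                 "-", end(gr)[i + 1L])
        }
    }
    if (any(gr$score < 0))
        stop("bedGraph signal values must be nonnegative")
    SignalTrack(gr)
}

#' Write a SignalTrack to bedGraph
#'
#' @param track A [SignalTrack-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSignalTrack <- function(track, path) {
    stopifnot(is(track, "SignalTrack"))
    rtracklayer::export(trackCoverage(track), path, format = "bedGraph")
    invisible(path)
}

#' Read a gene table (TSV) into a TSS GRanges
#'
#' Expects a header row with columns `gene_id`, `chrom`, `tss`, `strand`,
#' `expression`. `tss` is a 0-based base offset (BED convention); the result
#' is a width-1 GRanges at the TSS with `gene_id` and `expression` metadata.
#'
#' @param path Path to the TSV file.
#' @return A [GenomicRanges::GRanges] of width-1 TSS positions.
#' @export
readGeneTable <- function(path) {
    stopifnot(file.exists(path))
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand", "expression")
    if (!all(need %in% names(df)))
        stop("gene table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id in gene table: ",
             df$gene_id[duplicated(df$gene_id)][1L])
    if (any(df$expression < 0))
        stop("expression values must be nonnegative")
    GRanges(df$chrom, IRanges(df$tss + 1L, width = 1L),
            strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"),
            gene_id = df$gene_id, expression = df$expression)
}

#' Write a gene TSS GRanges back to the gene-table TSV format
#'
#' @param genes A width-1 [GenomicRanges::GRanges] with `gene_id` and
#'   `expression` metadata, as returned by [readGeneTable()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
    df <- data.frame(gene_id = genes$gene_id,
                     chrom = as.character(seqnames(genes)),
                     tss = start(genes) - 1L,
                     strand = {
                         s <- as.character(strand(genes))
                         s[s == "*"] <- "+"
                         s
                     },
                     expression = genes$expression)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene x cell-line dependency matrix with lineage labels
#'
#' The matrix TSV has a header of cell-line ids and one row per gene (first
#' column `gene_id`); the labels TSV has columns `cell_line`, `lineage`.
#'
#' @param matrixPath Path to the score matrix TSV.
#' @param labelsPath Path to the lineage label TSV.
#' @return A list with `scores` (numeric matrix, genes x lines) and
#'   `lineage` (named character vector over lines).
#' @export
readDependencyMatrix <- function(matrixPath, labelsPath) {
    df <- read.table(matrixPath, header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1L] != "gene_id")
        stop("dependency matrix must have 'gene_id' as its first column")
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene ids in dependency matrix")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    lab <- read.table(labelsPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (!all(c("cell_line", "lineage") %in% names(lab)))
        stop("labels table must have columns cell_line, lineage")
    lineage <- setNames(lab$lineage, lab$cell_line)
    missing <- setdiff(colnames(m), names(lineage))
    if (length(missing))
        stop("cell lines without lineage label: ",
             paste(missing, collapse = ", "))
    list(scores = m, lineage = lineage[colnames(m)])
}

#' Read a per-cell-line drug response (IC50) table
#'
#' Columns: `cell_line`, `lineage`, `ic50` (positive, consistent units).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the three columns.
#' @export
readIC50Table <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (!all(c("cell_line", "lineage", "ic50") %in% names(df)))
        stop("IC50 table must have columns cell_line, lineage, ic50")
    if (any(df$ic50 <= 0))
        stop("IC50 values must be positive")
    df
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop("GMT line ", bad[1L], " has fewer than 3 fields")
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(fields, `[[`, "", 1L)
    sets
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that keeps only the
#' first word of each sequence name.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
    seqs <- readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs
}
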