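## Assignment of transcriptionally active genes to enhancers within a
## distance window, and the SUPER/TYPICAL gene-set partition.

#' Assign active genes to enhancers within a window
#'
#' A link (enhancer, gene) exists iff the gene's expression is at least
#' `expressionThreshold` and the gap between the gene TSS and the enhancer
#' region boundary is at most `windowBp` (0 when the TSS lies inside the
#' enhancer). A gene may link to several enhancers.
#'
#' @param ranking A classified [EnhancerRanking-class].
#' @param genes Gene TSS [GenomicRanges::GRanges] with `gene_id` and
#'   `expression` metadata (see [readGeneTable()]).
#' @param windowBp Maximum TSS-to-enhancer distance in bp (default 50000,
#'   the conventional looping distance).
#' @param expressionThreshold Minimum expression for a gene to count as
#'   transcriptionally active (default 1.0 on the input scale).
#' @return A [GeneAssignment-class].
#' @export
assignGenes <- function(ranking, genes, windowBp = 50000,
                        expressionThreshold = 1.0) {
    stopifnot(is(ranking, "EnhancerRanking"), is(genes, "GRanges"))
    if (windowBp < 0) stop("windowBp must be nonnegative")
    enh <- ranking@enhancers
    if (all(is.na(enh$klass)))
        stop("classify the ranking with callSuperEnhancers() first")
    active <- genes[genes$expression >= expressionThreshold]
    hits <- findOverlaps(granges(active), granges(enh),
                         maxgap = windowBp, ignore.strand = TRUE)
    if (length(hits)) {
        g <- queryHits(hits); e <- subjectHits(hits)
        dist <- intervalRelate(granges(active)[g], granges(enh)[e])$distance
        links <- DataFrame(
            enhancer_id = enh$enhancer_id[e],
            gene_id = active$gene_id[g],
            distance = dist,
            klass = enh$klass[e])
        links <- links[order(links$enhancer_id, links$gene_id), , drop = FALSE]
        rownames(links) <- NULL
    } else {
        links <- DataFrame(enhancer_id = character(), gene_id = character(),
                           distance = numeric(), klass = character())
    }
    super_genes <- sort(unique(links$gene_id[links$klass == "SUPER"]))
    typical_genes <- sort(setdiff(unique(links$gene_id), super_genes))
    new("GeneAssignment",
        links = links,
        superGenes = super_genes,
        typicalGenes = typical_genes,
        window = windowBp,
        expressionThreshold = expressionThreshold)
}

#' Class-partitioned gene sets of an assignment
#'
#' SUPER-associated genes are those with at least one link to a SUPER
#' enhancer; TYPICAL-associated genes link only to typical enhancers. The
#' two sets are disjoint and cover exactly the linked genes.
#'
#' @param assignment A [GeneAssignment-class].
#' @return A list with character vectors `super_genes` and `typical_genes`
#'   and counts `n_super_genes`, `n_typical_genes`.
#' @export
classGeneSets <- function(assignment) {
    stopifnot(is(assignment, "GeneAssignment"))
    list(super_genes = assignment@superGenes,
         typical_genes = assignment@typicalGenes,
         n_super_genes = length(assignment@superGenes),
         n_typical_genes = length(assignment@typicalGenes))
}
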