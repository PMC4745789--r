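## Screen integration: lineage-selective dependency scoring on a gene x
## cell-line matrix, drug-sensitivity comparison, and the three-way screen
## intersection.

#' Lineage-selective dependency scoring by signal-to-noise ratio
#'
#' For every gene, `snr = (mu_target - mu_other) / (sigma_target +
#' sigma_other)` across cell lines, with each group standard deviation
#' floored at `max(0.2 * |mu of its group|, 1e-8)` (the standard
#' signal-to-noise convention for expression/dependency data). Genes are
#' ranked ascending by SNR: rank 1 is the most selectively depleted in the
#' target lineage (most negative SNR). Per-gene significance comes from
#' random relabeling of cell lines: `p = (1 + #\{snr_perm <= snr_obs\}) /
#' (1 + nPermutations)` (one-sided toward selective depletion).
#'
#' @param dependency A list with `scores` (numeric gene x line matrix) and
#'   `lineage` (character vector over lines), as from
#'   [readDependencyMatrix()]; or just the matrix, with `lineage` supplied
#'   separately.
#' @param targetLineage Lineage label of the target group (e.g.
#'   `"EWING"`); both groups need at least 2 lines.
#' @param lineage Optional lineage vector when `dependency` is a matrix.
#' @param nPermutations Number of label permutations (at least 100;
#'   default 1000).
#' @param seed Integer RNG seed (default 17).
#' @return A data.frame (one row per gene, ordered by rank) with columns
#'   `gene_id`, `snr`, `rank`, `p_value`, plus attributes `n_permutations`
#'   and `seed`.
#' @export
signalToNoiseSelectivity <- function(dependency, targetLineage,
                                     lineage = NULL,
                                     nPermutations = 1000L, seed = 17L) {
    if (is.list(dependency) && !is.null(dependency$scores)) {
        m <- dependency$scores
        lineage <- dependency$lineage
    } else {
        m <- dependency
    }
    stopifnot(is.matrix(m), !is.null(lineage),
              length(lineage) == ncol(m))
    if (nPermutations < 100L) stop("nPermutations must be at least 100")
    target <- lineage == targetLineage
    if (!any(target)) stop("target lineage '", targetLineage,
                           "' absent from the labels")
    if (sum(target) < 2L || sum(!target) < 2L)
        stop("need at least 2 cell lines per lineage group")
    groupSd <- function(x) {
        n <- ncol(x)
        mu <- rowMeans(x)
        sqrt(pmax(0, (rowSums(x * x) - n * mu * mu) / (n - 1)))
    }
    snrFor <- function(tmask) {
        xt <- m[, tmask, drop = FALSE]
        xo <- m[, !tmask, drop = FALSE]
        mt <- rowMeans(xt); mo <- rowMeans(xo)
        st <- pmax(groupSd(xt), 0.2 * abs(mt), 1e-8)
        so <- pmax(groupSd(xo), 0.2 * abs(mo), 1e-8)
        (mt - mo) / (st + so)
    }
    snr <- snrFor(target)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    count_le <- integer(nrow(m))
    for (i in seq_len(nPermutations)) {
        perm <- logical(ncol(m))
        perm[sample.int(ncol(m), sum(target))] <- TRUE
        count_le <- count_le + (snrFor(perm) <= snr)
    }
    p <- (1 + count_le) / (1 + nPermutations)
    o <- order(snr, rownames(m))
    out <- data.frame(gene_id = rownames(m)[o],
                      snr = snr[o],
                      rank = seq_along(o),
                      p_value = p[o],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "n_permutations") <- as.integer(nPermutations)
    attr(out, "seed") <- as.integer(seed)
    out
}

#' Compare drug sensitivity between lineages
#'
#' One-sided Mann-Whitney test that the target lineage has lower IC50
#' (greater sensitivity) than the other lines. Log-scale summaries are
#' reported; the rank test itself is transform-invariant.
#'
#' @param ic50 A data.frame with columns `cell_line`, `lineage`, `ic50`
#'   (see [readIC50Table()]).
#' @param targetLineage Label of the sensitive candidate lineage.
#' @param alternative Passed to [mannWhitney()] comparing target vs other;
#'   default `"less"` (target IC50 lower).
#' @return A list with group sizes, median IC50s, `p_value` and `test`.
#' @export
drugSensitivityTest <- function(ic50, targetLineage,
                                alternative = "less") {
    stopifnot(all(c("lineage", "ic50") %in% names(ic50)))
    x <- ic50$ic50[ic50$lineage == targetLineage]
    y <- ic50$ic50[ic50$lineage != targetLineage]
    if (!length(x) || !length(y))
        stop("both lineage groups must be non-empty")
    mw <- mannWhitney(x, y, alternative = alternative)
    list(n_target = length(x), n_other = length(y),
         median_target = median(x), median_other = median(y),
         mean_log_target = mean(log(x)), mean_log_other = mean(log(y)),
         p_value = mw$p.value, test = mw)
}

#' Intersect the three screening approaches
#'
#' Returns the seven disjoint regions of the Venn diagram of the
#' super-enhancer gene set, the dependency-screen hit set and the
#' drug-validated set, with the triple intersection highlighted. Ids within
#' each region are sorted for deterministic output.
#'
#' @param seGenes,dependencyHits,drugValidated Character vectors of gene
#'   ids.
#' @return A list of class `"VennRegions"` with the seven disjoint regions
#'   (`se_only`, `dependency_only`, `drug_only`, `se_dependency`,
#'   `se_drug`, `dependency_drug`, `triple`) and `counts`.
#' @export
integrateHits <- function(seGenes, dependencyHits, drugValidated) {
    A <- unique(as.character(seGenes))
    B <- unique(as.character(dependencyHits))
    C <- unique(as.character(drugValidated))
    regions <- list(
        se_only = setdiff(A, union(B, C)),
        dependency_only = setdiff(B, union(A, C)),
        drug_only = setdiff(C, union(A, B)),
        se_dependency = setdiff(intersect(A, B), C),
        se_drug = setdiff(intersect(A, C), B),
        dependency_drug = setdiff(intersect(B, C), A),
        triple = intersect(intersect(A, B), C))
    regions <- lapply(regions, sort)
    structure(c(regions, list(counts = vapply(regions, length, 0L))),
              class = "VennRegions")
}

#' @export
print.VennRegions <- function(x, ...) {
    cat("Three-screen intersection (disjoint Venn regions):\n")
    for (nm in names(x$counts))
        cat(sprintf("  %-16s %d\n", nm, x$counts[[nm]]))
    if (length(x$triple))
        cat("  triple hits:", paste(x$triple, collapse = ", "), "\n")
    invisible(x)
}
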