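## Gene-set enrichment on the enhancer-signal ranking: weighted
## Kolmogorov-Smirnov-like running sum, gene-set permutation null, and the
## SUPER vs TYPICAL expression comparison.

#' Rank genes by the signal of their linked enhancers
#'
#' Per-gene metric = maximum signal over the gene's linked enhancers
#' ("genes with high H3K27Ac binding signal in their enhancer regions");
#' genes are sorted by descending metric, ties broken lexicographically by
#' gene id. Genes with no links are excluded (their count is reported in
#' the `n_unlinked` attribute).
#'
#' @param assignment A [GeneAssignment-class].
#' @param ranking The [EnhancerRanking-class] the assignment was built
#'   from.
#' @return A data.frame with columns `gene_id` and `metric`, sorted by
#'   descending metric.
#' @export
rankGenesByEnhancerSignal <- function(assignment, ranking) {
    stopifnot(is(assignment, "GeneAssignment"), is(ranking, "EnhancerRanking"))
    links <- assignment@links
    enh <- ranking@enhancers
    sig <- setNames(enh$signal, enh$enhancer_id)
    if (!all(links$enhancer_id %in% names(sig)))
        stop("assignment links carry enhancer ids absent from the ranking")
    if (!nrow(links))
        return(structure(data.frame(gene_id = character(), metric = numeric()),
                         n_unlinked = 0L))
    metric <- tapply(sig[links$enhancer_id], links$gene_id, max)
    df <- data.frame(gene_id = names(metric), metric = as.numeric(metric),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$metric, df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
    df
}

## ES from hit positions within a ranked list; metric must be the full
## descending metric vector. Returns the signed extremum and, optionally,
## the full running sum.
.esFromHits <- function(metric, hitIdx, weightExponent, runningSum = FALSE) {
    N <- length(metric)
    s <- length(hitIdx)
    hitIdx <- sort(hitIdx)
    w <- abs(metric[hitIdx])^weightExponent
    sw <- sum(w)
    if (sw == 0) w[] <- 1 / s else w <- w / sw
    missDec <- if (N == s) 0 else 1 / (N - s)
    if (runningSum) {
        step <- rep(-missDec, N)
        step[hitIdx] <- w
        rs <- cumsum(step)
        es <- rs[which.max(abs(rs))]
        return(list(es = es, running_sum = rs))
    }
    ## extrema can only occur at a hit (local max) or just before the next
    ## hit (local min), so the full N-vector is not needed
    cumw <- cumsum(w)
    missesBefore <- hitIdx - seq_len(s)
    atHit <- cumw - missesBefore * missDec
    beforeNext <- c(0, cumw[-s]) - missesBefore * missDec
    lastDrop <- cumw[s] - (N - hitIdx[s] + missesBefore[s]) * missDec
    cand <- c(atHit, beforeNext, lastDrop)
    cand[which.max(abs(cand))]
}

#' GSEA enrichment score
#'
#' Walks the descending ranked list; a hit (gene in the set) adds
#' `|metric|^weightExponent / sum_set |metric|^weightExponent`, a miss
#' subtracts `1/(N - N_set)`. The enrichment score is the running-sum value
#' of maximal absolute deviation from zero (signed).
#'
#' @param ranked A data.frame from [rankGenesByEnhancerSignal()] (columns
#'   `gene_id`, `metric`, descending metric), or a named numeric metric
#'   vector sorted in decreasing order.
#' @param geneSet Character vector of gene ids; must intersect the list and
#'   not cover it entirely.
#' @param weightExponent Nonnegative weight on the metric (default 1, the
#'   classic weighted statistic; 0 gives the unweighted KS form).
#' @return A list with `es` and `running_sum` (length = list size).
#' @export
enrichmentScore <- function(ranked, geneSet, weightExponent = 1) {
    r <- .asRankedList(ranked)
    if (weightExponent < 0) stop("weightExponent must be nonnegative")
    hitIdx <- which(r$gene_id %in% geneSet)
    if (!length(hitIdx))
        stop("gene set is disjoint from the ranked list")
    res <- .esFromHits(r$metric, hitIdx, weightExponent, runningSum = TRUE)
    list(es = res$es, running_sum = res$running_sum)
}

.asRankedList <- function(ranked) {
    if (is.data.frame(ranked)) {
        stopifnot(all(c("gene_id", "metric") %in% names(ranked)))
        r <- list(gene_id = as.character(ranked$gene_id),
                  metric = as.numeric(ranked$metric))
    } else {
        stopifnot(is.numeric(ranked), !is.null(names(ranked)))
        r <- list(gene_id = names(ranked), metric = as.numeric(ranked))
    }
    if (anyDuplicated(r$gene_id)) stop("ranked gene ids must be unique")
    if (is.unsorted(rev(r$metric)))
        stop("ranked metric must be non-increasing")
    r
}

#' GSEA significance by gene-set permutation
#'
#' Null distribution: enrichment scores of random gene sets of the same
#' size drawn without replacement from the ranked list (gene-set
#' permutation -- the ranking derives from one sample's enhancer signal, so
#' there are no phenotype labels to permute).
#' `p = (1 + #\{|es_null| >= |es_obs|\}) / (1 + n_permutations)`;
#' `nes = es_obs / mean(|es_null| over null scores with the sign of
#' es_obs)`. Reproducible given `seed`.
#'
#' @inheritParams enrichmentScore
#' @param nPermutations Number of permutations (at least 100; default 1000).
#' @param seed Integer RNG seed recorded in the result (default 17).
#' @return A list of class `"GseaResult"`: `es`, `nes`, `p_value`,
#'   `running_sum`, `n_permutations`, `seed`, `set_size`.
#' @export
gseaPermutation <- function(ranked, geneSet, weightExponent = 1,
                            nPermutations = 1000L, seed = 17L) {
    if (nPermutations < 100L) stop("nPermutations must be at least 100")
    r <- .asRankedList(ranked)
    obs <- enrichmentScore(setNames(r$metric, r$gene_id),
                           geneSet, weightExponent)
    s <- sum(r$gene_id %in% geneSet)
    N <- length(r$gene_id)
    if (s >= N) stop("gene set size must be smaller than the list")
    null_es <- numeric(nPermutations)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    for (i in seq_len(nPermutations))
        null_es[i] <- .esFromHits(r$metric, sample.int(N, s), weightExponent)
    p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + nPermutations)
    same_sign <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
    structure(list(
        es = obs$es, nes = nes, p_value = p,
        running_sum = obs$running_sum,
        n_permutations = as.integer(nPermutations),
        seed = as.integer(seed), set_size = s
    ), class = "GseaResult")
}

#' @export
print.GseaResult <- function(x, ...) {
    cat("GSEA result: ES = ", format(x$es, digits = 4),
        ", NES = ", format(x$nes, digits = 4),
        ", p = ", format(x$p_value, digits = 4),
        " (", x$n_permutations, " gene-set permutations, set size ",
        x$set_size, ", seed ", x$seed, ")\n", sep = "")
    invisible(x)
}

## save/restore the global RNG state so seeded helpers do not perturb the
## caller's stream
.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}
.Random.seed_restore <- function(old) {
    if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv())
}

#' Expression comparison between SUPER- and TYPICAL-associated genes
#'
#' Summarizes expression per gene class and tests whether SUPER-associated
#' genes are more highly expressed with a one-sided Mann-Whitney test
#' (SUPER > TYPICAL).
#'
#' @param genes Gene TSS [GenomicRanges::GRanges] with `gene_id` and
#'   `expression` metadata.
#' @param assignment A [GeneAssignment-class]; both gene classes must be
#'   non-empty.
#' @return A list with per-class summaries (`n`, `median`, `q1`, `q3`) and
#'   `test` (the [mannWhitney()] `"htest"`, `NULL` when a class has a
#'   single gene) plus `p_value`.
#' @export
expressionByClass <- function(genes, assignment) {
    stopifnot(is(genes, "GRanges"), is(assignment, "GeneAssignment"))
    expr <- setNames(genes$expression, genes$gene_id)
    sg <- assignment@superGenes; tg <- assignment@typicalGenes
    if (!length(sg) || !length(tg))
        stop("both gene classes must be non-empty")
    xs <- expr[sg]; xt <- expr[tg]
    summ <- function(v) list(n = length(v), median = median(v),
                             q1 = unname(quantile(v, 0.25)),
                             q3 = unname(quantile(v, 0.75)))
    res <- list(super = summ(xs), typical = summ(xt),
                test = NULL, p_value = NA_real_)
    if (length(xs) >= 2L && length(xt) >= 2L) {
        mw <- mannWhitney(xs, xt, alternative = "greater")
        res$test <- mw
        res$p_value <- mw$p.value
    }
    res
}
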