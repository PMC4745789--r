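## Seeded synthetic-data generator. Emulates the statistical structure of a
## super-enhancer screening study: a hockey-stick enhancer signal landscape
## (many ~2 kb typical enhancers, few ~30 kb super-enhancers carrying
## heavy-tailed signal), GGAA microsatellites and FLI1 binding biased into
## super-enhancers, target genes near super-enhancers with elevated
## expression, and lineage-selective dependency / drug-sensitivity screens.
## One master seed; each component draws from a fixed-offset sub-stream so
## adding a component never perturbs earlier draws.

## centered window around each range, clamped to [1, seqlength] without
## transient out-of-bound ranges
.centeredWindow <- function(gr, width) {
    mid <- (start(gr) + end(gr)) %/% 2L
    half <- (width - 1L) %/% 2L
    sl <- seqlengths(seqinfo(gr))[as.character(seqnames(gr))]
    sl[is.na(sl)] <- .Machine$integer.max
    GRanges(seqnames(gr),
            IRanges(pmax(1L, mid - half),
                    pmin(as.integer(sl), mid + (width - 1L) - half)),
            seqinfo = seqinfo(gr))
}

.SEED_LAYOUT <- 101L
.SEED_SEQUENCE <- 202L
.SEED_TRACKS <- 303L
.SEED_SCREENS <- 404L
.SEED_EXPRESSION <- 505L

#' Configuration for the synthetic dataset generator
#'
#' Returns the generator configuration with documented defaults. Lengths
#' are in bp, densities in RPM per base. The defaults describe the study
#' conditions the pipeline is validated on: 1000 typical enhancers (median
#' ~2 kb), 20 super-enhancers (median ~30 kb, ~10x signal density with a
#' heavy-tailed multiplier), GGAA microsatellites and FLI1 binding enriched
#' in super-enhancers (FLI1-resident runs averaging ~7.3 repeats vs ~2.3
#' elsewhere), one elevated-expression target gene within 50 kb of each
#' super-enhancer, and a 40-line screen with 5 planted Ewing-selective
#' dependency genes and a 0.2x IC50 shift in the target lineage.
#'
#' @param seed Master RNG seed (default 17). Component sub-streams are
#'   derived from it by fixed offsets.
#' @param ... Overrides for any default field; unknown names are an error.
#' @return A list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(seed = 17L, ...) {
    cfg <- list(
        seed = as.integer(seed),
        ## genome layout
        n_chromosomes = 4L,
        chrom_length = 8e6,
        spacing_bp = 25000,          # 2x default stitch distance
        jitter_bp = 5000,
        ## enhancer classes
        n_typical = 1000L,
        n_super = 20L,
        typical_length_meanlog = log(2000), typical_length_sdlog = 0.3,
        super_length_meanlog = log(30000), super_length_sdlog = 0.25,
        super_constituents_min = 3L, super_constituents_max = 8L,
        ## signal model
        lambda_bg = 0.02,            # background density, RPM/base
        lambda_enh = 0.5,            # typical enhancer density, RPM/base
        typical_strength_sdlog = 0.3,
        super_strength_factor = 10,
        super_strength_pareto_alpha = 3,
        bin_bp = 50L,                # counting-noise bin width
        ## microsatellites / FLI1
        msat_per_super = 3,
        msat_per_typical = 0.4,
        msat_bg_per_mb = 20,
        fli1_prob_enh = 0.55,
        fli1_prob_bg = 0.05,
        repeats_in_fli1_mean = 7.3,
        repeats_out_mean = 2.3,
        fli1_peak_halfwidth = 150,
        ## genes and expression
        n_genes = 1200L,
        typical_proximal_fraction = 0.6,
        gene_clear_margin = 3000,    # keep TSSs this far from enhancer edges
        expr_meanlog = 1, expr_sdlog = 0.8,
        se_expr_shift = 1.5,         # meanlog shift for SE target genes
        decoy_tss_peak_fraction = 0.3,
        tss_k4me3_halfwidth = 1000,
        ## screens
        target_lineage = "EWING",
        n_lines = 40L,
        n_target_lines = 10L,
        n_screen_genes = 500L,
        n_selective_genes = 5L,
        dependency_effect = -2,
        ic50_meanlog = log(5), ic50_sdlog = 1,
        ic50_shift_factor = 0.2,
        n_drug_validated_extra = 3L)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    structure(cfg, class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
    cat("SyntheticConfig (seed ", x$seed, "): ",
        x$n_typical, " typical + ", x$n_super, " super enhancers on ",
        x$n_chromosomes, " x ", format(x$chrom_length, big.mark = ","),
        " bp; ", x$n_genes, " genes; ", x$n_lines, " screen lines\n",
        sep = "")
    invisible(x)
}

## fast random DNA of length n
.randomDna <- function(n) {
    rawToChar(as.raw(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)]))
}

#' Generate the synthetic genomic landscape
#'
#' Lays out enhancers (with constituent peaks), microsatellites, FLI1
#' binding sites and genes on a random genome, deterministically for a
#' given seed. Enhancers are spaced by at least `spacing_bp` (twice the
#' default stitch distance), so stitching at the default distance recovers
#' exactly the planted enhancers. GGAA/TTCC runs are written into the
#' sequence at their planted coordinates; FLI1-resident runs draw longer
#' repeat counts.
#'
#' @param config A [syntheticConfig()].
#' @param sequence Generate the genome sequence (default `TRUE`). With
#'   `FALSE` only coordinates and truth are produced, which is much faster
#'   when no sequence-level analysis is needed.
#' @return A list of class `"SyntheticTruth"`: `config`, `enhancers`
#'   (GRanges with `klass`, `strength`, `true_id`), `constituents`
#'   (GRangesList), `microsatellites` (GRanges with `unit`,
#'   `repeat_count`, `in_fli1`), `fli1_peaks` (GRanges), `genes` (TSS
#'   GRanges with `gene_id`, `expression`, `se_target`), `se_target_genes`
#'   (character), and `genome` ([Biostrings::DNAStringSet] or `NULL`).
#' @export
generateLandscape <- function(config = syntheticConfig(), sequence = TRUE) {
    stopifnot(inherits(config, "SyntheticConfig"))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed + .SEED_LAYOUT)
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    seqinfo <- Seqinfo(chroms, rep(config$chrom_length, length(chroms)))

    ## -- enhancer layout ---------------------------------------------------
    ne <- config$n_typical + config$n_super
    klass <- sample(c(rep("SUPER", config$n_super),
                      rep("TYPICAL", config$n_typical)))
    len <- ifelse(klass == "SUPER",
                  pmax(5000, round(rlnorm(ne, config$super_length_meanlog,
                                          config$super_length_sdlog))),
                  pmax(500, round(rlnorm(ne, config$typical_length_meanlog,
                                         config$typical_length_sdlog))))
    chrom_of <- rep(seq_along(chroms), length.out = ne)
    starts <- integer(ne)
    for (ci in seq_along(chroms)) {
        idx <- which(chrom_of == ci)
        pos <- config$spacing_bp
        for (i in idx) {
            pos <- pos + round(runif(1, 0, config$jitter_bp))
            starts[i] <- pos
            pos <- pos + len[i] + config$spacing_bp
        }
        if (pos > config$chrom_length - config$spacing_bp)
            stop("infeasible packing: enhancers need ", pos + config$spacing_bp,
                 " bp on ", chroms[ci], " but chrom_length is ",
                 config$chrom_length,
                 " (limiting constraint: chrom_length vs n enhancers x ",
                 "(length + spacing_bp))")
    }
    enh <- GRanges(chroms[chrom_of], IRanges(starts, width = len),
                   seqinfo = seqinfo)
    strength <- config$lambda_enh *
        rlnorm(ne, 0, config$typical_strength_sdlog)
    is_super <- klass == "SUPER"
    ## heavy-tailed (Pareto) multiplier on top of the x10 factor
    pareto <- (1 - runif(sum(is_super)))^(-1 / config$super_strength_pareto_alpha)
    strength[is_super] <- strength[is_super] * config$super_strength_factor *
        pareto
    enh$klass <- klass
    enh$strength <- strength
    enh$true_id <- sprintf("true_enh_%04d", seq_len(ne))

    ## constituent peaks: typical = the region; super = several peaks with
    ## gaps well under the stitch distance
    cs_start <- vector("list", ne)
    cs_width <- vector("list", ne)
    for (i in seq_len(ne)) {
        if (!is_super[i] || len[i] < 5 * 500) {
            cs_start[[i]] <- starts[i]
            cs_width[[i]] <- len[i]
            next
        }
        k <- sample(config$super_constituents_min:config$super_constituents_max, 1L)
        gaps <- round(runif(k - 1L, 200, 2000))
        avail <- len[i] - sum(gaps)
        if (avail < k * 300) {
            cs_start[[i]] <- starts[i]
            cs_width[[i]] <- len[i]
            next
        }
        cuts <- sort(runif(k - 1L, 0.2, 0.8))
        w <- round(diff(c(0, cuts, 1)) * avail)
        w[w < 300] <- 300
        cs_start[[i]] <- starts[i] + c(0, cumsum(w[-k] + gaps))
        cs_width[[i]] <- w
    }
    all_const <- GRanges(rep(chroms[chrom_of], lengths(cs_start)),
                         IRanges(unlist(cs_start), width = unlist(cs_width)),
                         seqinfo = seqinfo)
    constituents <- relist(all_const, cs_start)

    ## -- microsatellites and FLI1 sites ------------------------------------
    msat <- .plantMicrosatellites(enh, config, chroms, seqinfo)

    fli1 <- msat[msat$in_fli1]
    fli1_peaks <- if (length(fli1)) {
        gr <- granges(fli1)
        GRanges(seqnames(gr),
                IRanges(pmax(1, start(gr) - config$fli1_peak_halfwidth),
                        pmin(config$chrom_length,
                             end(gr) + config$fli1_peak_halfwidth)),
                seqinfo = seqinfo)
    } else GRanges(seqinfo = seqinfo)

    ## -- genes -------------------------------------------------------------
    genes <- .plantGenes(enh, config, chroms, seqinfo)
    set.seed(config$seed + .SEED_EXPRESSION)
    meanlog <- ifelse(genes$se_target,
                      config$expr_meanlog + config$se_expr_shift,
                      config$expr_meanlog)
    genes$expression <- round(rlnorm(length(genes), meanlog,
                                     config$expr_sdlog), 4)

    ## -- genome sequence ---------------------------------------------------
    genome <- NULL
    if (sequence) {
        set.seed(config$seed + .SEED_SEQUENCE)
        seqs <- lapply(chroms, function(ch) .randomDna(config$chrom_length))
        genome <- DNAStringSet(unlist(seqs))
        names(genome) <- chroms
        for (ci in seq_along(chroms)) {
            mm <- msat[as.character(seqnames(msat)) == chroms[ci]]
            if (!length(mm)) next
            genome[[ci]] <- Biostrings::replaceAt(
                genome[[ci]],
                IRanges(start(mm), end(mm)),
                DNAStringSet(strrep(mm$unit, mm$repeat_count)))
        }
    }

    structure(list(
        config = config,
        enhancers = enh,
        constituents = constituents,
        microsatellites = msat,
        fli1_peaks = fli1_peaks,
        genes = genes,
        se_target_genes = genes$gene_id[genes$se_target],
        genome = genome
    ), class = "SyntheticTruth")
}

## place GGAA/TTCC runs inside enhancers (class-specific rates) and in the
## background, with FLI1 membership and conditional repeat counts
.plantMicrosatellites <- function(enh, config, chroms, seqinfo) {
    is_super <- enh$klass == "SUPER"
    rate <- ifelse(is_super, config$msat_per_super, config$msat_per_typical)
    counts <- rpois(length(enh), rate)
    enh_chrom <- as.character(seqnames(enh))
    enh_start <- start(enh)
    enh_width <- width(enh)
    recs <- list()
    withmsat <- which(counts > 0)
    if (length(withmsat)) {
        pos_list <- lapply(withmsat, function(i) {
            k <- counts[i]
            ## one run per equal slot of the region keeps runs disjoint
            slot <- floor(enh_width[i] / k)
            if (slot < 200) {
                k <- max(1L, floor(enh_width[i] / 200))
                slot <- floor(enh_width[i] / k)
            }
            enh_start[i] + (seq_len(k) - 1L) * slot +
                round(runif(k, 0, max(0, slot - 120)))
        })
        recs[[1L]] <- data.frame(
            chrom = rep(enh_chrom[withmsat], lengths(pos_list)),
            pos = unlist(pos_list),
            in_enh = TRUE)
    }
    ## background runs outside enhancers
    n_bg <- rpois(1, config$msat_bg_per_mb *
                     config$n_chromosomes * config$chrom_length / 1e6)
    if (n_bg > 0) {
        bg_chrom <- sample(chroms, n_bg, replace = TRUE)
        bg_pos <- round(runif(n_bg, 1000, config$chrom_length - 1000))
        bg <- GRanges(bg_chrom, IRanges(bg_pos, width = 120))
        keep <- !overlapsAny(bg, enh + 1000, ignore.strand = TRUE)
        recs[[length(recs) + 1L]] <- data.frame(
            chrom = bg_chrom[keep], pos = bg_pos[keep], in_enh = FALSE)
    }
    df <- do.call(rbind, recs)
    if (is.null(df) || !nrow(df)) {
        gr <- GRanges(seqinfo = seqinfo)
        gr$unit <- character(); gr$repeat_count <- integer()
        gr$in_fli1 <- logical()
        return(gr)
    }
    p_fli1 <- ifelse(df$in_enh, config$fli1_prob_enh, config$fli1_prob_bg)
    in_fli1 <- runif(nrow(df)) < p_fli1
    lam <- ifelse(in_fli1, config$repeats_in_fli1_mean - 2,
                  config$repeats_out_mean - 2)
    repeats <- 2L + rpois(nrow(df), pmax(0, lam))
    minus <- runif(nrow(df)) < 0.5
    gr <- GRanges(df$chrom, IRanges(df$pos, width = 4L * repeats),
                  strand = ifelse(minus, "-", "+"), seqinfo = seqinfo)
    gr$unit <- ifelse(minus, "TTCC", "GGAA")
    gr$repeat_count <- repeats
    gr$in_fli1 <- in_fli1
    ## drop the rare run that would cross a chromosome end or a neighbour
    gr <- gr[end(gr) <= config$chrom_length]
    gr <- gr[!duplicated(findOverlaps(gr, reduce(granges(gr)),
                                      select = "first"))]
    sort(gr, ignore.strand = TRUE)
}

## one target gene within 50 kb of every super-enhancer, a fraction of the
## rest near typical enhancers, the remainder uniform background; TSSs are
## kept clear of every enhancer (plus margin) so promoter exclusion never
## deletes a planted constituent
.plantGenes <- function(enh, config, chroms, seqinfo) {
    is_super <- enh$klass == "SUPER"
    n_super <- sum(is_super)
    n_rest <- config$n_genes - n_super
    if (n_rest < 0) stop("n_genes must be at least n_super")
    n_typ_prox <- round(config$typical_proximal_fraction * n_rest)
    forbidden <- reduce(enh + config$gene_clear_margin)
    clear <- function(chrom, pos) {
        !overlapsAny(GRanges(chrom, IRanges(pos, width = 1L)), forbidden,
                     ignore.strand = TRUE)
    }
    place_near <- function(regions) {
        n <- length(regions)
        pos <- rep(NA_real_, n)
        todo <- seq_len(n)
        for (try in 1:50) {
            if (!length(todo)) break
            side <- sample(c(-1, 1), length(todo), replace = TRUE)
            ## > margin so the TSS clears the flanked enhancer itself
            dist <- round(runif(length(todo), config$gene_clear_margin + 500,
                                40000))
            cand <- ifelse(side < 0, start(regions)[todo] - dist,
                           end(regions)[todo] + dist)
            cand <- pmin(pmax(cand, 1), config$chrom_length)
            ok <- clear(as.character(seqnames(regions))[todo], cand)
            pos[todo[ok]] <- cand[ok]
            todo <- todo[!ok]
        }
        if (length(todo))
            stop("infeasible packing: could not place genes near enhancers ",
                 "clear of other enhancers (limiting constraint: ",
                 "gene_clear_margin vs spacing_bp)")
        pos
    }
    sup <- enh[is_super]
    pos_super <- place_near(sup)
    chrom_super <- as.character(seqnames(sup))
    typ_idx <- sample(which(!is_super), n_typ_prox, replace = TRUE)
    pos_typ <- place_near(enh[typ_idx])
    chrom_typ <- as.character(seqnames(enh))[typ_idx]
    n_bg <- n_rest - n_typ_prox
    chrom_bg <- sample(chroms, n_bg, replace = TRUE)
    pos_bg <- round(runif(n_bg, 1, config$chrom_length))
    for (try in 1:50) {
        bad <- which(!clear(chrom_bg, pos_bg))
        if (!length(bad)) break
        pos_bg[bad] <- round(runif(length(bad), 1, config$chrom_length))
    }
    chrom <- c(chrom_super, chrom_typ, chrom_bg)
    pos <- c(pos_super, pos_typ, pos_bg)
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = strand,
                  seqinfo = seqinfo)
    gr$gene_id <- sprintf("gene_%04d", seq_along(gr))
    gr$se_target <- c(rep(TRUE, n_super), rep(FALSE, n_typ_prox + n_bg))
    gr
}

#' Simulate the ChIP-seq signal track and peak files
#'
#' Per-base expected density is `lambda_bg` plus the planted strength over
#' every constituent peak; the realized track draws Poisson counts per
#' `bin_bp` bin and rescales to RPM per base (coverage granularity without
#' read-level simulation). H3K27Ac peaks are the planted constituents plus
#' decoy peaks at a fraction of TSSs (to exercise the TSS/H3K4me3
#' exclusion); H3K4me3 peaks sit at every TSS; FLI1 peaks come from the
#' planted truth.
#'
#' @param truth A `"SyntheticTruth"` from [generateLandscape()].
#' @param config The same [syntheticConfig()] (defaults to
#'   `truth$config`).
#' @return A list: `track` ([SignalTrack-class]), `k27ac_peaks`,
#'   `k4me3_peaks`, `fli1_peaks` (GRanges with `name`/`score`).
#' @export
simulateTracksAndPeaks <- function(truth, config = truth$config) {
    stopifnot(inherits(truth, "SyntheticTruth"))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed + .SEED_TRACKS)
    chroms <- seqlevels(truth$enhancers)
    bin <- config$bin_bp
    nbin <- ceiling(config$chrom_length / bin)
    const <- unlist(truth$constituents, use.names = FALSE)
    const$strength <- rep(truth$enhancers$strength,
                          lengths(truth$constituents))
    ## decoy H3K27Ac peaks at a fraction of TSSs
    genes <- truth$genes
    n_decoy <- round(config$decoy_tss_peak_fraction * length(genes))
    decoy_idx <- if (n_decoy > 0) sample(length(genes), n_decoy) else integer()
    decoys <- if (length(decoy_idx)) {
        .centeredWindow(granges(genes[decoy_idx]), 1000L)
    } else GRanges()
    if (length(decoys)) decoys$strength <- config$lambda_enh
    cov_segments <- list()
    for (ci in seq_along(chroms)) {
        lam <- rep(config$lambda_bg, nbin)
        add_strength <- function(regions, strengths) {
            sel <- as.character(seqnames(regions)) == chroms[ci]
            rs <- start(regions)[sel]; re <- end(regions)[sel]
            stg <- strengths[sel]
            for (j in seq_along(rs)) {
                b0 <- (rs[j] - 1L) %/% bin + 1L
                b1 <- (re[j] - 1L) %/% bin + 1L
                if (b0 == b1) {
                    lam[b0] <<- lam[b0] + stg[j] * (re[j] - rs[j] + 1) / bin
                } else {
                    lam[b0] <<- lam[b0] + stg[j] * (b0 * bin - rs[j] + 1) / bin
                    lam[b1] <<- lam[b1] + stg[j] * (re[j] - (b1 - 1L) * bin) / bin
                    if (b1 - b0 > 1L) {
                        mid <- (b0 + 1L):(b1 - 1L)
                        lam[mid] <<- lam[mid] + stg[j]
                    }
                }
            }
        }
        add_strength(const, const$strength)
        if (length(decoys)) add_strength(decoys, decoys$strength)
        val <- rpois(nbin, lam * bin) / bin
        nz <- which(val > 0)
        if (length(nz))
            cov_segments[[length(cov_segments) + 1L]] <- data.frame(
                chrom = chroms[ci],
                start = (nz - 1L) * bin + 1L,
                end = pmin(nz * bin, config$chrom_length),
                score = val[nz])
    }
    cov <- if (length(cov_segments)) {
        df <- do.call(rbind, cov_segments)
        GRanges(df$chrom, IRanges(df$start, df$end), score = df$score)
    } else GRanges(score = numeric())
    track <- SignalTrack(cov)
    k27 <- sort(c(granges(const), granges(decoys)), ignore.strand = TRUE)
    k27$name <- sprintf("k27ac_pk_%05d", seq_along(k27))
    k27$score <- 0
    k4 <- .centeredWindow(granges(genes),
                          2L * as.integer(config$tss_k4me3_halfwidth) + 1L)
    strand(k4) <- "*"
    k4 <- sort(k4)
    k4$name <- sprintf("k4me3_pk_%05d", seq_along(k4))
    k4$score <- 0
    fli1 <- granges(truth$fli1_peaks)
    strand(fli1) <- "*"
    fli1 <- sort(fli1)
    if (length(fli1)) {
        fli1$name <- sprintf("fli1_pk_%05d", seq_along(fli1))
        fli1$score <- 0
    }
    list(track = track, k27ac_peaks = k27, k4me3_peaks = k4,
         fli1_peaks = fli1)
}

#' Simulate expression and screen tables
#'
#' Dependency scores are standard normal with a negative shift
#' (`dependency_effect`) for the planted selective genes in target-lineage
#' lines; IC50s are log-normal with a multiplicative downward shift
#' (`ic50_shift_factor`) for the target lineage. The screened gene universe
#' is a sample of the landscape's genes that always includes the
#' super-enhancer target genes; the planted selective genes are drawn from
#' those targets.
#'
#' @param truth A `"SyntheticTruth"` from [generateLandscape()].
#' @param config The same [syntheticConfig()] (defaults to `truth$config`).
#' @return A list: `expression` (data.frame gene_id/expression),
#'   `dependency` (list `scores`, `lineage` as in
#'   [readDependencyMatrix()]), `ic50` (data.frame), `selective_genes`,
#'   `drug_validated` (character vectors).
#' @export
simulateExpressionAndScreens <- function(truth, config = truth$config) {
    stopifnot(inherits(truth, "SyntheticTruth"))
    if (config$n_lines < 4L)
        stop("n_lines must be at least 4 (2 per lineage group)")
    if (config$n_target_lines < 2L ||
        config$n_lines - config$n_target_lines < 2L)
        stop("need at least 2 cell lines per lineage group")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed + .SEED_SCREENS)
    genes <- truth$genes
    se_targets <- truth$se_target_genes
    n_screen <- min(config$n_screen_genes, length(genes))
    pool <- setdiff(genes$gene_id, se_targets)
    screen_genes <- sort(c(se_targets,
                           sample(pool, max(0, n_screen - length(se_targets)))))
    n_sel <- min(config$n_selective_genes, length(se_targets))
    selective <- sort(sample(se_targets, n_sel))
    lines <- sprintf("line_%02d", seq_len(config$n_lines))
    lineage <- setNames(rep("OTHER", config$n_lines), lines)
    lineage[seq_len(config$n_target_lines)] <- config$target_lineage
    m <- matrix(rnorm(length(screen_genes) * config$n_lines),
                nrow = length(screen_genes),
                dimnames = list(screen_genes, lines))
    target_cols <- lineage == config$target_lineage
    m[selective, target_cols] <- m[selective, target_cols] +
        config$dependency_effect
    m <- round(m, 4)
    ic50 <- rlnorm(config$n_lines, config$ic50_meanlog, config$ic50_sdlog)
    ic50[target_cols] <- ic50[target_cols] * config$ic50_shift_factor
    ic50_df <- data.frame(cell_line = lines,
                          lineage = unname(lineage),
                          ic50 = round(ic50, 6))
    n_extra <- min(config$n_drug_validated_extra,
                   length(setdiff(screen_genes, selective)))
    drug_validated <- sort(c(selective,
                             sample(setdiff(screen_genes, selective), n_extra)))
    list(expression = data.frame(gene_id = genes$gene_id,
                                 expression = genes$expression),
         dependency = list(scores = m, lineage = lineage),
         ic50 = ic50_df,
         selective_genes = selective,
         drug_validated = drug_validated)
}

#' Generate and (optionally) write a complete synthetic dataset
#'
#' Convenience wrapper: [generateLandscape()] +
#' [simulateTracksAndPeaks()] + [simulateExpressionAndScreens()], and, when
#' `dir` is given, writes every file of the external dataset contract:
#' `genome.fa`, `genes.tsv`, `k27ac.bedgraph`, `k27ac_peaks.bed`,
#' `k4me3_peaks.bed`, `fli1_peaks.bed`, `expression.tsv`,
#' `dependency.tsv`, `labels.tsv`, `ic50.tsv`, `truth.json`.
#'
#' @param config A [syntheticConfig()].
#' @param dir Output directory (created if needed), or `NULL` to keep
#'   everything in memory.
#' @param sequence Whether to generate the genome sequence (see
#'   [generateLandscape()]).
#' @return A list with `truth`, `tracks` (see [simulateTracksAndPeaks()]),
#'   `screens` (see [simulateExpressionAndScreens()]) and `files` (named
#'   paths, when written).
#' @export
simulateDataset <- function(config = syntheticConfig(), dir = NULL,
                            sequence = TRUE) {
    truth <- generateLandscape(config, sequence = sequence)
    tracks <- simulateTracksAndPeaks(truth, config)
    screens <- simulateExpressionAndScreens(truth, config)
    files <- NULL
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        files <- c(
            genes = file.path(dir, "genes.tsv"),
            k27ac_track = file.path(dir, "k27ac.bedgraph"),
            k27ac_peaks = file.path(dir, "k27ac_peaks.bed"),
            k4me3_peaks = file.path(dir, "k4me3_peaks.bed"),
            fli1_peaks = file.path(dir, "fli1_peaks.bed"),
            expression = file.path(dir, "expression.tsv"),
            dependency = file.path(dir, "dependency.tsv"),
            labels = file.path(dir, "labels.tsv"),
            ic50 = file.path(dir, "ic50.tsv"),
            truth = file.path(dir, "truth.json"))
        writeGeneTable(truth$genes, files[["genes"]])
        writeSignalTrack(tracks$track, files[["k27ac_track"]])
        writePeaks(tracks$k27ac_peaks, files[["k27ac_peaks"]])
        writePeaks(tracks$k4me3_peaks, files[["k4me3_peaks"]])
        writePeaks(tracks$fli1_peaks, files[["fli1_peaks"]])
        write.table(screens$expression, files[["expression"]], sep = "\t",
                    quote = FALSE, row.names = FALSE)
        dep <- data.frame(gene_id = rownames(screens$dependency$scores),
                          screens$dependency$scores, check.names = FALSE)
        write.table(dep, files[["dependency"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(data.frame(cell_line = names(screens$dependency$lineage),
                               lineage = unname(screens$dependency$lineage)),
                    files[["labels"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(screens$ic50, files[["ic50"]], sep = "\t",
                    quote = FALSE, row.names = FALSE)
        if (sequence) {
            files <- c(files, genome = file.path(dir, "genome.fa"))
            writeXStringSet(truth$genome, files[["genome"]])
        }
        .writeTruthJson(truth, screens, files[["truth"]])
    }
    list(truth = truth, tracks = tracks, screens = screens, files = files)
}

.writeTruthJson <- function(truth, screens, path) {
    enh <- truth$enhancers
    msat <- truth$microsatellites
    out <- list(
        seed = truth$config$seed,
        enhancers = data.frame(
            true_id = enh$true_id,
            chrom = as.character(seqnames(enh)),
            start = start(enh) - 1L, end = end(enh),
            klass = enh$klass, strength = round(enh$strength, 6)),
        microsatellites = data.frame(
            chrom = as.character(seqnames(msat)),
            start = start(msat) - 1L,
            unit = msat$unit, repeat_count = msat$repeat_count,
            in_fli1 = msat$in_fli1),
        se_target_genes = truth$se_target_genes,
        selective_genes = screens$selective_genes,
        drug_validated = screens$drug_validated)
    write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
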