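## End-to-end orchestration: one config (YAML or list), stages in
## dependency order, structured logs, a machine-readable summary and a
## manifest with file digests for reproducibility checks.

.pipelineDefaults <- function() list(
    seed = 17L,
    simulate = FALSE,
    synthetic = list(),
    inputs = list(),
    params = list(
        tss_exclusion = 2500,
        k4me3_overlap_fraction = 0.5,
        stitch = 12500,
        se_method = "tangent",
        top_n = NULL,
        window = 50000,
        min_expression = 1.0,
        msat_unit = "GGAA",
        min_repeats = 2L,
        body_bins = 50L,
        flank = 5000L,
        flank_bins = 25L,
        weight_exponent = 1,
        nperm_gsea = 1000L,
        nperm_snr = 1000L,
        target_lineage = "EWING",
        selectivity_p = 0.05))

#' Run the full super-enhancer screening pipeline
#'
#' Executes, in dependency order: simulate (optional) -> super-enhancer
#' calling -> gene assignment -> microsatellite scan and enrichment ->
#' metagene profiles -> GSEA -> screen integration. Each stage writes its
#' outputs under `outDir`; a `summary.json` with the headline numbers and a
#' `manifest.json` with per-file md5 digests, stage timings and the warning
#' tally are written at the end. Rerunning with an identical config and
#' seed reproduces identical digests for all outputs.
#'
#' @param config A configuration list or path to a YAML file. Top-level
#'   fields: `seed`; `simulate` (logical; when `TRUE` the `synthetic`
#'   block overrides [syntheticConfig()] fields and all inputs are
#'   self-generated under `outDir/simdata`); `inputs` (paths:
#'   `k27ac_peaks`, `k27ac_track`, `k4me3_peaks`, `genes` required when
#'   not simulating; `fli1_peaks`, `genome`, `dependency`, `labels`,
#'   `ic50`, `gene_sets` (GMT), `drug_validated` optional -- stages whose
#'   inputs are absent are skipped); `params` (see
#'   defaults in the vignette).
#' @param outDir Output directory, created if needed.
#' @return Invisibly, a list with `summary`, `manifest` and the main
#'   in-memory results (`ranking`, `assignment`, ...).
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    cfg <- .pipelineDefaults()
    for (nm in intersect(names(config), c("seed", "simulate")))
        cfg[[nm]] <- config[[nm]]
    unknown <- setdiff(names(config),
                       c("seed", "simulate", "synthetic", "inputs", "params"))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg$synthetic <- config$synthetic %||% list()
    cfg$inputs <- config$inputs %||% list()
    for (nm in names(config$params %||% list())) {
        if (!nm %in% names(cfg$params))
            stop("unknown config field: params.", nm)
        cfg$params[[nm]] <- config$params[[nm]]
    }
    p <- cfg$params
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    n_warnings <- 0L
    timings <- list()
    outputs <- character()
    log <- function(stage, msg)
        message(sprintf("[%s] INFO %s", stage, msg))
    run_stage <- function(stage, expr) {
        t0 <- Sys.time()
        res <- withCallingHandlers(expr, warning = function(w) {
            n_warnings <<- n_warnings + 1L
            message(sprintf("[%s] WARN %s", stage, conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
        timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
        res
    }
    need_input <- function(name) {
        path <- cfg$inputs[[name]]
        if (is.null(path))
            stop("missing required input: inputs.", name, call. = FALSE)
        if (!file.exists(path))
            stop("input file not found: inputs.", name, " = ", path,
                 call. = FALSE)
        path
    }

    ## -- stage: simulate ---------------------------------------------------
    screens_truth <- NULL
    if (isTRUE(cfg$simulate)) {
        sim <- run_stage("simulate", {
            sc <- do.call(syntheticConfig,
                          c(list(seed = cfg$seed), cfg$synthetic))
            log("simulate", paste0("generating synthetic dataset (seed ",
                                   cfg$seed, ")"))
            simulateDataset(sc, dir = file.path(outDir, "simdata"))
        })
        cfg$inputs <- as.list(sim$files)
        screens_truth <- sim$screens
        outputs <- c(outputs, unlist(sim$files))
    }

    ## -- load inputs -------------------------------------------------------
    k27_peaks <- readPeaks(need_input("k27ac_peaks"))
    track <- readSignalTrack(need_input("k27ac_track"))
    k4_peaks <- readPeaks(need_input("k4me3_peaks"))
    genes <- readGeneTable(need_input("genes"))
    fli1 <- if (!is.null(cfg$inputs$fli1_peaks))
        readPeaks(cfg$inputs$fli1_peaks) else NULL
    genome <- if (!is.null(cfg$inputs$genome))
        readGenome(cfg$inputs$genome) else NULL
    control <- if (!is.null(cfg$inputs$control_track))
        readSignalTrack(cfg$inputs$control_track) else NULL

    ## -- stage: call-se ----------------------------------------------------
    ranking <- run_stage("call-se", {
        cand <- defineCandidates(k27_peaks, genes, k4_peaks,
                                 tssExclusionBp = p$tss_exclusion,
                                 k4me3OverlapFraction = p$k4me3_overlap_fraction)
        log("call-se", paste0(length(cand), "/", length(k27_peaks),
                              " peaks kept as distal enhancer candidates"))
        stitched <- stitchPeaks(cand, stitchDistanceBp = p$stitch)
        rk <- quantifyEnhancers(stitched, track, control = control)
        rk <- callSuperEnhancers(rk, method = p$se_method, n = p$top_n)
        log("call-se", paste0(length(rk@enhancers), " enhancers, ",
                              sum(rk@enhancers$klass == "SUPER"), " SUPER"))
        rk
    })
    enh <- ranking@enhancers
    enh$name <- enh$enhancer_id
    f_enh <- file.path(outDir, "enhancers.bed")
    writePeaks(enh, f_enh, extraColumns = c("rank", "klass"))
    summ <- summarizeRanking(ranking)
    f_rsum <- file.path(outDir, "ranking_summary.json")
    write_json(summ, f_rsum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, f_enh, f_rsum)

    ## -- stage: assign -----------------------------------------------------
    assignment <- run_stage("assign", {
        a <- assignGenes(ranking, genes, windowBp = p$window,
                         expressionThreshold = p$min_expression)
        log("assign", paste0(nrow(a@links), " links; ",
                             length(a@superGenes), " SE genes"))
        a
    })
    links <- as.data.frame(assignment@links)
    f_links <- file.path(outDir, "assignment_links.tsv")
    write.table(links, f_links, sep = "\t", quote = FALSE, row.names = FALSE)
    best <- links[order(links$gene_id, links$distance), ]
    best <- best[!duplicated(best$gene_id), c("gene_id", "enhancer_id",
                                              "distance", "klass")]
    gene_class <- ifelse(best$gene_id %in% assignment@superGenes,
                         "SUPER", "TYPICAL")
    best$klass <- gene_class
    f_genes <- file.path(outDir, "se_genes.tsv")
    write.table(best[order(best$klass, best$gene_id), ], f_genes,
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f_links, f_genes)

    ## -- stage: msat / enrich ----------------------------------------------
    msats <- NULL
    enrich_rows <- list()
    sup_gr <- granges(superEnhancers(ranking))
    typ_gr <- granges(typicalEnhancers(ranking))
    if (!is.null(genome)) {
        msats <- run_stage("msat", {
            ms <- scanMicrosatellites(genome, unit = p$msat_unit,
                                      minRepeats = p$min_repeats)
            log("msat", paste0(length(ms), " microsatellite runs"))
            ms
        })
        ms_bed <- msats
        ms_bed$name <- ms_bed$unit
        ms_bed$score <- ms_bed$repeat_count
        f_msat <- file.path(outDir, "microsatellites.bed")
        writePeaks(ms_bed, f_msat)
        outputs <- c(outputs, f_msat)
    }
    enrichment <- run_stage("enrich", {
        res <- list()
        if (length(sup_gr) && length(typ_gr)) {
            if (!is.null(fli1) && length(fli1)) {
                e <- regionOverlapEnrichment(sup_gr, typ_gr, fli1)
                res$fli1_peaks <- e
                enrich_rows[["fli1_peaks"]] <- .enrichRow("fli1_peak_overlap", e)
            }
            if (!is.null(msats) && length(msats)) {
                e <- regionOverlapEnrichment(sup_gr, typ_gr, msats)
                res$microsatellites <- e
                enrich_rows[["msat"]] <- .enrichRow("microsatellite_overlap", e)
            }
        }
        if (!is.null(msats) && length(msats) && !is.null(fli1) && length(fli1)) {
            rc <- repeatCountComparison(msats, fli1)
            res$repeat_counts <- rc
            enrich_rows[["rc"]] <- data.frame(
                test = "repeat_count_welch_t",
                statistic = if (!is.null(rc$test)) unname(rc$test$statistic) else NA,
                p_value = rc$p.value, a = rc$n_in, b = rc$n_out, c = NA, d = NA,
                group1_mean = rc$mean_in, group2_mean = rc$mean_out)
            log("enrich", sprintf(
                "GGAA repeats: mean %.2f in FLI1 peaks vs %.2f outside",
                rc$mean_in, rc$mean_out))
        }
        res
    })
    if (length(enrich_rows)) {
        f_enr <- file.path(outDir, "enrichment_results.tsv")
        write.table(do.call(rbind, enrich_rows), f_enr, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, f_enr)
    }

    ## -- stage: metagene ---------------------------------------------------
    metagenes <- run_stage("metagene", {
        out <- list()
        for (klass in c("SUPER", "TYPICAL")) {
            regions <- if (klass == "SUPER") sup_gr else typ_gr
            if (!length(regions)) next
            mp <- buildMetagene(regions, track, bodyBins = p$body_bins,
                                flankBp = p$flank, flankBins = p$flank_bins)
            f <- file.path(outDir,
                           paste0("metagene_", tolower(klass), ".tsv"))
            write.table(data.frame(bin = seq_along(mp$mean_signal),
                                   mean_signal = mp$mean_signal),
                        f, sep = "\t", quote = FALSE, row.names = FALSE)
            outputs <- c(outputs, f)
            out[[tolower(klass)]] <- mp
        }
        out
    })

    ## -- stage: gsea -------------------------------------------------------
    gsea <- run_stage("gsea", {
        ranked <- rankGenesByEnhancerSignal(assignment, ranking)
        sets <- NULL
        if (!is.null(cfg$inputs$gene_sets))
            sets <- readGmt(cfg$inputs$gene_sets)
        else if (!is.null(screens_truth))
            sets <- list(planted_se_targets =
                             readTruthField(cfg$inputs$truth,
                                            "se_target_genes"))
        if (is.null(sets) || !nrow(ranked)) {
            log("gsea", "no gene sets provided; stage skipped")
            NULL
        } else {
            res <- lapply(names(sets), function(nm) {
                gs <- intersect(sets[[nm]], ranked$gene_id)
                if (!length(gs) || length(gs) >= nrow(ranked)) return(NULL)
                g <- gseaPermutation(ranked, gs,
                                     weightExponent = p$weight_exponent,
                                     nPermutations = p$nperm_gsea,
                                     seed = cfg$seed)
                data.frame(set = nm, es = g$es, nes = g$nes,
                           p_value = g$p_value, set_size = g$set_size,
                           n_perm = g$n_permutations, seed = g$seed)
            })
            res <- do.call(rbind, res)
            if (!is.null(res)) {
                f <- file.path(outDir, "gsea_results.tsv")
                write.table(res, f, sep = "\t", quote = FALSE,
                            row.names = FALSE)
                outputs <- c(outputs, f)
                log("gsea", paste0(nrow(res), " gene set(s) tested"))
            }
            res
        }
    })

    ## -- stage: integrate --------------------------------------------------
    integration <- run_stage("integrate", {
        if (is.null(cfg$inputs$dependency) || is.null(cfg$inputs$labels)) {
            log("integrate", "no dependency screen inputs; stage skipped")
            NULL
        } else {
            dep <- readDependencyMatrix(cfg$inputs$dependency,
                                        cfg$inputs$labels)
            sel <- signalToNoiseSelectivity(dep, p$target_lineage,
                                            nPermutations = p$nperm_snr,
                                            seed = cfg$seed)
            f_sel <- file.path(outDir, "selectivity.tsv")
            write.table(sel, f_sel, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            outputs <- c(outputs, f_sel)
            drug <- NULL
            if (!is.null(cfg$inputs$ic50)) {
                ic50 <- readIC50Table(cfg$inputs$ic50)
                drug <- drugSensitivityTest(ic50, p$target_lineage)
                f_drug <- file.path(outDir, "drug_test.tsv")
                write.table(data.frame(
                    n_target = drug$n_target, n_other = drug$n_other,
                    median_target = drug$median_target,
                    median_other = drug$median_other,
                    U = unname(drug$test$statistic),
                    p_value = drug$p_value), f_drug, sep = "\t",
                    quote = FALSE, row.names = FALSE)
                outputs <- c(outputs, f_drug)
            }
            hits <- sel$gene_id[sel$p_value < p$selectivity_p & sel$snr < 0]
            drug_set <- if (!is.null(screens_truth))
                screens_truth$drug_validated
            else unlist(cfg$inputs$drug_validated) %||% character()
            venn <- integrateHits(assignment@superGenes, hits, drug_set)
            f_venn <- file.path(outDir, "venn_regions.json")
            write_json(unclass(venn), f_venn, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
            outputs <- c(outputs, f_venn)
            log("integrate", paste0(length(hits), " dependency hits; triple ",
                                    "intersection size ",
                                    length(venn$triple)))
            list(selectivity = sel, drug = drug, venn = venn)
        }
    })

    ## -- summary + manifest ------------------------------------------------
    summary <- list(
        seed = cfg$seed,
        n_enhancers = summ$n_enhancers,
        n_super = summ$n_super,
        super_signal_fraction = summ$super_signal_fraction,
        median_length_typical = summ$median_length_typical,
        median_length_super = summ$median_length_super,
        n_se_genes = length(assignment@superGenes),
        n_typical_genes = length(assignment@typicalGenes),
        fli1_odds_ratio = if (!is.null(enrichment$fli1_peaks))
            unname(enrichment$fli1_peaks$result$estimate) else NULL,
        fli1_p = if (!is.null(enrichment$fli1_peaks))
            enrichment$fli1_peaks$result$p.value else NULL,
        msat_odds_ratio = if (!is.null(enrichment$microsatellites))
            unname(enrichment$microsatellites$result$estimate) else NULL,
        msat_p = if (!is.null(enrichment$microsatellites))
            enrichment$microsatellites$result$p.value else NULL,
        ggaa_mean_in_fli1 = if (!is.null(enrichment$repeat_counts))
            enrichment$repeat_counts$mean_in else NULL,
        ggaa_mean_outside = if (!is.null(enrichment$repeat_counts))
            enrichment$repeat_counts$mean_out else NULL,
        gsea = if (!is.null(gsea))
            lapply(seq_len(nrow(gsea)), function(i)
                list(set = gsea$set[i], es = gsea$es[i], nes = gsea$nes[i],
                     p = gsea$p_value[i])) else NULL,
        top_selective_genes = if (!is.null(integration))
            head(integration$selectivity$gene_id, 10L) else NULL,
        drug_p = if (!is.null(integration$drug))
            integration$drug$p_value else NULL,
        triple_hits = if (!is.null(integration))
            integration$venn$triple else NULL)
    f_sum <- file.path(outDir, "summary.json")
    write_json(summary, f_sum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, f_sum)

    outputs <- unique(normalizePath(outputs))
    digests <- md5sum(outputs)
    rel <- outputs
    pre <- paste0(normalizePath(outDir), "/")
    rel[startsWith(rel, pre)] <- substring(rel[startsWith(rel, pre)],
                                           nchar(pre) + 1L)
    manifest <- list(
        config = cfg[c("seed", "simulate", "synthetic", "params")],
        inputs = cfg$inputs,
        outputs = lapply(seq_along(outputs), function(i)
            list(path = rel[i], md5 = unname(digests[i]))),
        stage_seconds = timings,
        n_warnings = n_warnings)
    f_man <- file.path(outDir, "manifest.json")
    write_json(manifest, f_man, auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(summary = summary, manifest = manifest,
                   ranking = ranking, assignment = assignment,
                   enrichment = enrichment, metagenes = metagenes,
                   gsea = gsea, integration = integration,
                   microsatellites = msats))
}

## read one field back from a written truth.json
readTruthField <- function(path, field) {
    if (is.null(path) || !file.exists(path)) return(NULL)
    unlist(read_json(path)[[field]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.enrichRow <- function(name, e) {
    data.frame(test = name,
               statistic = unname(e$result$estimate),
               p_value = e$result$p.value,
               a = e$table[1, 1], b = e$table[1, 2],
               c = e$table[2, 1], d = e$table[2, 2],
               group1_mean = NA, group2_mean = NA)
}
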