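#' Pipeline configuration
#'
#' Collects every input and parameter of an end-to-end scan. Variants
#' come either from a VCF + panel (`vcf`, `panel`, `par`) or from the
#' synthetic generator (`synthetic`); thresholds come either from fixed
#' values (`thresholds`) or from neutral calibration (`calibration`).
#'
#' @param outputDir run directory (created).
#' @param seed master seed; stage seeds are derived from it.
#' @param vcf,panel,par input paths (VCF, panel TSV, PAR BED), or NULL.
#' @param synthetic list(model, chromLengths, sweeps, nDogs, nWolves,
#'   nAncient, blockSize), or NULL.
#' @param calibration list(model, chromLengths, reps, blockSize) for the
#'   neutral null, or NULL when `thresholds` is given.
#' @param thresholds optional list(fst, hp, xpclr) of fixed thresholds.
#' @param fstWin,fstStep,minSnps F_ST window parameters.
#' @param xpclr an [xpclrConfig()].
#' @param xpclrWin,xpclrStep,minGrids XP-CLR averaging parameters.
#' @param hpQ,dhpQ Hp simulation percentile and genome-wide deltaHp
#'   percentile.
#' @param q upper-tail percentile for F_ST / XP-CLR calibration.
#' @param enrichment list(genes, annotation, ontology, N, flank), or
#'   NULL.
#' @param runCnv scan depth tracks when the cohort carries them.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(outputDir, seed = 1, vcf = NULL, panel = NULL,
                           par = NULL, synthetic = NULL, calibration = NULL,
                           thresholds = NULL, fstWin = 200000,
                           fstStep = 50000, minSnps = 10,
                           xpclr = xpclrConfig(), xpclrWin = 25000,
                           xpclrStep = 10000, minGrids = 5, hpQ = 0.1,
                           dhpQ = 5, q = 99, enrichment = NULL,
                           runCnv = TRUE) {
    if (is.null(vcf) && is.null(synthetic))
        stop("config needs either 'vcf' (+'panel') or 'synthetic'")
    if (!is.null(vcf)) {
        for (f in c(vcf, panel)) if (!is.null(f) && !file.exists(f))
            stop("input path does not exist: ", f)
    }
    if (is.null(thresholds) && is.null(calibration))
        stop("config needs either fixed 'thresholds' or a 'calibration' block")
    structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full domestication-scan pipeline
#'
#' Stages: acquire variants (load or simulate) -> site filters and allele
#' frequencies -> calibrate thresholds on neutral simulations -> windowed
#' F_ST scan with Hp/deltaHp filters and merging -> XP-CLR scan with the
#' same filters -> optional V_ST copy-number scan -> optional enrichment.
#' All outputs (window TSVs, region BEDs, a JSON manifest with per-stage
#' counts, seeds and thresholds) are written under `config$outputDir`;
#' identical config and seed reproduce identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the main result objects and the
#'   manifest.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed
    manifest <- list(seed = seed, thresholds = list(), counts = list())
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    # --- variants -----------------------------------------------------
    acq <- stage("variants", {
        if (!is.null(config$vcf)) {
            pn <- readPanel(config$panel)
            par <- if (!is.null(config$par))
                rtracklayer::import(config$par, format = "BED") else NULL
            list(vt = loadVariants(config$vcf, pn, par), cohort = NULL)
        } else {
            sy <- config$synthetic
            co <- generateCohort(sy$model, sy$chromLengths,
                sweeps = sy$sweeps, nDogs = sy$nDogs %||% 43,
                nWolves = sy$nWolves %||% 10,
                nAncient = sy$nAncient %||% 2, seed = seed,
                blockSize = sy$blockSize %||% 20000)
            co <- generateAncientSamples(co,
                nAncient = sy$nAncient %||% 2, seed = seed + 1)
            list(vt = cohortVariants(co), cohort = co)
        }
    })
    vt <- acq$vt
    cohort <- acq$cohort
    manifest$counts$sites_loaded <- nrow(vt)
    vt <- stage("maf_filter", mafFilter(vt))
    manifest$counts$sites_after_maf <- nrow(vt)
    freqs <- stage("allele_frequencies", alleleFrequencies(vt))
    chromLengths <- GenomeInfoDb::seqlengths(rowRanges(vt))

    ancientGt <- if (!is.null(cohort) && !is.null(ancientGenotypes(cohort))) {
        keep <- match(paste0(freqs$chrom, ":", freqs$pos),
                      paste0(seqnames(rowRanges(cohortVariants(cohort))), ":",
                             start(rowRanges(cohortVariants(cohort)))))
        ancientGenotypes(cohort)[keep, , drop = FALSE]
    } else NULL

    # --- calibration --------------------------------------------------
    thr <- config$thresholds
    if (is.null(thr)) {
        cal <- config$calibration
        sims <- stage("neutral_simulation",
            simulateNeutral(cal$model, cal$chromLengths,
                            reps = cal$reps %||% 25, seed = seed + 1000,
                            blockSize = cal$blockSize %||% 20000))
        sims <- lapply(sims, mafFilter)
        calChrom <- cal$chromLengths
        fstCal <- stage("calibrate_fst", calibrateThreshold(function(s) {
            f <- siteFst(alleleFrequencies(s))
            w <- windowedFst(f, makeWindows(calChrom, config$fstWin,
                                            config$fstStep),
                             minSnps = config$minSnps)
            mcols(w)$value
        }, sims, config$q, statistic = "fst"))
        hpCal <- stage("calibrate_hp", calibrateThreshold(function(s) {
            w <- windowHp(alleleFrequencies(s),
                          makeWindows(calChrom, config$xpclrWin,
                                      config$xpclrStep))
            mcols(w)$hp
        }, sims, config$hpQ, statistic = "hp"))
        xpCal <- stage("calibrate_xpclr", calibrateThreshold(function(s) {
            g <- xpclrScoreGrid(alleleFrequencies(s), calChrom,
                                config$xpclr)
            w <- averageGridWindows(g, calChrom, config$xpclrWin,
                                    config$xpclrStep, config$minGrids)
            mcols(w)$value
        }, sims, config$q, statistic = "xpclr"))
        thr <- list(fst = calibratedThreshold(fstCal),
                    hp = calibratedThreshold(hpCal),
                    xpclr = calibratedThreshold(xpCal))
    }
    manifest$thresholds <- thr

    # --- F_ST scan ----------------------------------------------------
    sites <- stage("site_fst", siteFst(freqs))
    fstWindows <- stage("windowed_fst", {
        w <- windowedFst(sites, makeWindows(chromLengths, config$fstWin,
                                            config$fstStep),
                         minSnps = config$minSnps)
        if (!is.null(ancientGt)) deltaHp(freqs, ancientGt, w)
        else windowHp(freqs, w)
    })
    manifest$counts$fst_windows_tested <-
        sum(mcols(fstWindows)$pass_support)
    passFst <- !is.na(mcols(fstWindows)$value) &
        mcols(fstWindows)$value > thr$fst
    manifest$counts$fst_windows_significant <- sum(passFst)
    dhpThrFst <- if (!is.null(ancientGt))
        percentileThreshold(mcols(fstWindows)$deltaHp[
            !is.na(mcols(fstWindows)$deltaHp)], 100 - config$dhpQ) else NULL
    fstMerge <- stage("fst_filter_merge", {
        if (!is.null(ancientGt)) {
            fw <- applyHpFilters(fstWindows, thr$hp, dhpThrFst)
            keep <- passFst & mcols(fw)$pass_hp_all
        } else {
            keep <- passFst & !is.na(mcols(fstWindows)$hp) &
                mcols(fstWindows)$hp < thr$hp
        }
        list(regions = mergeRegions(fstWindows[keep], maxGap = 0),
             nAfter = sum(keep))
    })
    fstRegions <- fstMerge$regions
    manifest$counts$fst_windows_after_hp <- fstMerge$nAfter
    manifest$counts$fst_regions <- length(fstRegions)

    # --- XP-CLR scan --------------------------------------------------
    grid <- stage("xpclr_grid",
        xpclrScoreGrid(freqs, chromLengths, config$xpclr))
    xpWindows <- stage("xpclr_windows", {
        w <- averageGridWindows(grid, chromLengths, config$xpclrWin,
                                config$xpclrStep, config$minGrids)
        if (!is.null(ancientGt)) deltaHp(freqs, ancientGt, w)
        else windowHp(freqs, w)
    })
    manifest$counts$xpclr_windows_tested <-
        sum(mcols(xpWindows)$pass_support)
    passXp <- !is.na(mcols(xpWindows)$value) &
        mcols(xpWindows)$value > thr$xpclr
    manifest$counts$xpclr_windows_significant <- sum(passXp)
    xpMerge <- stage("xpclr_filter_merge", {
        if (!is.null(ancientGt)) {
            dhpThrXp <- percentileThreshold(mcols(xpWindows)$deltaHp[
                !is.na(mcols(xpWindows)$deltaHp)], 100 - config$dhpQ)
            xw <- applyHpFilters(xpWindows, thr$hp, dhpThrXp)
            keep <- passXp & mcols(xw)$pass_hp_all
        } else {
            keep <- passXp & !is.na(mcols(xpWindows)$hp) &
                mcols(xpWindows)$hp < thr$hp
        }
        list(regions = mergeRegions(xpWindows[keep], maxGap = 50000),
             nAfter = sum(keep))
    })
    xpRegions <- xpMerge$regions
    manifest$counts$xpclr_windows_after_hp <- xpMerge$nAfter
    manifest$counts$xpclr_regions <- length(xpRegions)

    # --- copy number --------------------------------------------------
    vstRegions <- NULL
    if (config$runCnv && !is.null(cohort) && !is.null(cohortDepth(cohort))) {
        vstRegions <- stage("cnv_scan", {
            dp <- gcCorrectDepth(cohortDepth(cohort), minBin = 20)
            cn <- estimateCopyNumber(dp)
            callVstOutliers(vstScan(cn))
        })
        manifest$counts$vst_regions <- length(vstRegions)
    }

    # --- enrichment ---------------------------------------------------
    enrich <- NULL
    if (!is.null(config$enrichment) && length(xpRegions)) {
        en <- config$enrichment
        enrich <- stage("enrichment", {
            onto <- buildOntology(en$annotation, en$ontology)
            regions <- xpRegions
            GenomeInfoDb::seqlengths(regions) <-
                chromLengths[GenomeInfoDb::seqlevels(regions)]
            permutationPvalues(regions, en$genes, onto,
                               N = en$N %||% 1000, seed = seed + 2000,
                               flank = en$flank %||% 50000)
        })
        manifest$counts$enriched_terms <-
            nrow(filterEnrichedTerms(enrich))
    }

    # --- outputs ------------------------------------------------------
    out <- config$outputDir
    writeWindowTsv(fstWindows, file.path(out, "fst_windows.tsv"))
    writeRegionsBed(fstRegions, file.path(out, "fst_regions.bed"))
    writeWindowTsv(xpWindows, file.path(out, "xpclr_windows.tsv"))
    writeRegionsBed(xpRegions, file.path(out, "xpclr_regions.bed"))
    if (!is.null(vstRegions))
        writeRegionsBed(vstRegions, file.path(out, "vst_regions.bed"))
    if (!is.null(enrich))
        utils::write.table(enrich, file.path(out, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(variants = vt, fstWindows = fstWindows,
                   fstRegions = fstRegions, xpclrWindows = xpWindows,
                   xpclrRegions = xpRegions, vstRegions = vstRegions,
                   enrichment = enrich, thresholds = thr,
                   manifest = manifest, cohort = cohort))
}
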