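#' Read windowed depth tracks into a DepthProfiles object
#'
#' Depth tracks are bedGraph/BED4 files (chrom, start, end, depth), one
#' per sample, over a common window set; window GC fractions come from a
#' matching bedGraph.
#'
#' @param depthPaths named character vector of per-sample bedGraph paths
#'   (names = sample IDs).
#' @param gcPath bedGraph of per-window GC fractions on the same windows.
#' @param panel sample panel data.frame covering all samples.
#' @param controlRegions optional GRanges of copy-number control regions;
#'   windows fully inside them are flagged `control`.
#' @param parIntervals optional PAR GRanges for X region classes.
#' @return A [DepthProfiles-class].
#' @export
readDepthTracks <- function(depthPaths, gcPath, panel,
                            controlRegions = NULL, parIntervals = NULL) {
    panel <- validatePanel(panel)
    if (is.null(names(depthPaths))) stop("depthPaths must be named by sample")
    gc <- rtracklayer::import(gcPath, format = "bedGraph")
    win <- granges(gc)
    depth <- sapply(depthPaths, function(p) {
        tr <- rtracklayer::import(p, format = "bedGraph")
        if (length(tr) != length(win) ||
            !all(granges(tr) == win))
            stop("depth track ", p, " does not match the GC window set")
        tr$score
    })
    mcols(win)$gc <- gc$score
    mcols(win)$control <- if (is.null(controlRegions))
        rep(TRUE, length(win))
    else IRanges::overlapsAny(win, controlRegions, type = "within")
    mcols(win)$regionClass <- regionClassOf(win, parIntervals)
    panel <- panel[match(colnames(depth), panel$sample), , drop = FALSE]
    cd <- DataFrame(population = panel$population, sex = panel$sex,
                    row.names = panel$sample)
    methods::new("DepthProfiles",
        SummarizedExperiment(assays = list(depth = depth),
                             rowRanges = win, colData = cd))
}

#' GC-correct windowed depth
#'
#' Bins control windows by GC fraction (1% bins) per sample and rescales
#' each window by `global control mean / control mean of its GC bin`, so
#' flat-GC input is unchanged. Windows falling in a GC bin with fewer than
#' `minBin` control windows cannot be corrected and are flagged
#' (`corrected = NA`).
#'
#' @param dp A [DepthProfiles-class]; `rowRanges()$control` marks the
#'   control windows used to fit the curve.
#' @param binWidth GC bin width (default 0.01).
#' @param minBin minimum control windows per usable bin (default 100).
#' @return `dp` with a `corrected` assay added.
#' @export
gcCorrectDepth <- function(dp, binWidth = 0.01, minBin = 100) {
    depth <- assay(dp, "depth")
    ctrl <- rowRanges(dp)$control
    if (is.null(ctrl)) stop("rowRanges(dp)$control is required")
    if (!any(ctrl)) stop("no control windows designated")
    bin <- floor(rowRanges(dp)$gc / binWidth)
    corrected <- matrix(NA_real_, nrow(depth), ncol(depth),
                        dimnames = dimnames(depth))
    binCounts <- table(bin[ctrl])
    usable <- as.numeric(names(binCounts))[binCounts >= minBin]
    ok <- bin %in% usable
    for (s in seq_len(ncol(depth))) {
        gmean <- mean(depth[ctrl, s])
        bmean <- tapply(depth[ctrl, s], bin[ctrl], mean)
        fac <- gmean / bmean[as.character(bin)]
        corrected[ok, s] <- depth[ok, s] * fac[ok]
    }
    assays(dp)$corrected <- corrected
    dp
}

#' Convert corrected depth to copy-number estimates
#'
#' Per sample, `CN = 2 * corrected depth / mean corrected depth over
#' control windows`, anchoring the control regions at copy number two.
#'
#' @param dp A [DepthProfiles-class] with a `corrected` assay (or raw
#'   depth if no GC correction was applied).
#' @return A [CopyNumberTable-class].
#' @export
estimateCopyNumber <- function(dp) {
    a <- if ("corrected" %in% assayNames(dp)) "corrected" else "depth"
    d <- assay(dp, a)
    ctrl <- rowRanges(dp)$control
    if (is.null(ctrl) || !any(ctrl)) stop("control windows required")
    cn <- d
    for (s in seq_len(ncol(d))) {
        m <- mean(d[ctrl, s], na.rm = TRUE)
        if (!is.finite(m) || m == 0) stop("zero control-window mean for ",
                                          colnames(d)[s])
        cn[, s] <- 2 * d[, s] / m
    }
    rr <- rowRanges(dp)
    keep <- c("control", "regionClass")
    mcols(rr) <- mcols(rr)[intersect(keep, names(mcols(rr)))]
    if (is.null(mcols(rr)$regionClass))
        mcols(rr)$regionClass <- regionClassOf(rr)
    methods::new("CopyNumberTable",
        SummarizedExperiment(assays = list(CN = cn), rowRanges = rr,
                             colData = colData(dp)))
}

#' Per-sample signal-to-noise ratio
#'
#' Mean depth over autosomal control windows divided by its (sample)
#' standard deviation.
#'
#' @param dp A [DepthProfiles-class].
#' @param useCorrected use the corrected assay when available.
#' @return named numeric vector of SNR values.
#' @export
sampleSnr <- function(dp, useCorrected = TRUE) {
    a <- if (useCorrected && "corrected" %in% assayNames(dp))
        "corrected" else "depth"
    d <- assay(dp, a)
    ctrl <- rowRanges(dp)$control & rowRanges(dp)$regionClass == "autosome"
    if (sum(ctrl) < 2) stop("need >= 2 autosomal control windows")
    apply(d[ctrl, , drop = FALSE], 2, function(x) {
        x <- x[!is.na(x)]
        s <- stats::sd(x)
        if (s == 0) stop("constant control depths: SNR undefined")
        mean(x) / s
    })
}

# population variance with denominator N
popVar <- function(x) mean((x - mean(x))^2)

#' V_ST copy-number differentiation per window
#'
#' `V_ST = (V_T - V_S) / V_T`, where `V_T` is the variance of all
#' samples' copy numbers and `V_S` the size-weighted mean of the
#' within-population (dog, wolf) variances; population variances use
#' denominator N so identical distributions give exactly 0. Estimated
#' male copy numbers in the X-nonPAR are doubled before the calculation.
#' Windows with `V_T = 0` emit no value.
#'
#' @param cn A [CopyNumberTable-class] with dog and wolf samples.
#' @return GRanges of windows with `vt`, `vs`, `vst`, `cnRange`,
#'   `regionClass`.
#' @export
vstScan <- function(cn) {
    cd <- colData(cn)
    dog <- cd$population == "dog"
    wolf <- cd$population == "wolf"
    if (sum(dog) < 2 || sum(wolf) < 2)
        stop("V_ST needs >= 2 samples in each population")
    m <- assay(cn, "CN")[, dog | wolf, drop = FALSE]
    isDog <- cd$population[dog | wolf] == "dog"
    male <- cd$sex[dog | wolf] == "male"
    rc <- rowRanges(cn)$regionClass
    nonpar <- rc == "X-nonPAR"
    if (any(nonpar) && any(male))
        m[nonpar, male] <- 2 * m[nonpar, male, drop = FALSE]
    nd <- sum(isDog); nw <- sum(!isDog)
    vT <- apply(m, 1, popVar)
    vD <- apply(m[, isDog, drop = FALSE], 1, popVar)
    vW <- apply(m[, !isDog, drop = FALSE], 1, popVar)
    vS <- (vD * nd + vW * nw) / (nd + nw)
    vst <- ifelse(vT > 0, (vT - vS) / vT, NA_real_)
    out <- granges(rowRanges(cn))
    mcols(out) <- DataFrame(vt = vT, vs = vS, vst = vst,
                            cnRange = apply(m, 1, max) - apply(m, 1, min),
                            regionClass = rc)
    out
}

#' Call V_ST outlier regions
#'
#' Z-transforms V_ST within the autosome+X-PAR and X-nonPAR partitions
#' (windows without a value excluded), keeps windows with a copy-number
#' range of at least `minCnRange` across all samples and Z > 5
#' (autosome/X-PAR) or Z > 3 (X-nonPAR), merges adjacent passing windows,
#' and discards regions spanning only a single window.
#'
#' @param records GRanges from [vstScan()].
#' @param minCnRange minimum copy-number range (default 1.5).
#' @param zAuto,zNonPar Z cutoffs (strictly greater).
#' @return GRanges of outlier regions with `peak` and `nWindows`.
#' @export
callVstOutliers <- function(records, minCnRange = 1.5, zAuto = 5,
                            zNonPar = 3) {
    ok <- !is.na(mcols(records)$vst)
    rec <- zTransform(records[ok], valueColumn = "vst")
    z <- mcols(rec)$zscore
    rc <- mcols(rec)$regionClass
    cut <- ifelse(rc == "X-nonPAR", zNonPar, zAuto)
    pass <- !is.na(z) & z > cut & mcols(rec)$cnRange >= minCnRange
    mcols(rec)$value <- mcols(rec)$vst
    merged <- mergeRegions(rec[pass], maxGap = 0)
    merged[mcols(merged)$nWindows >= 2]
}
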