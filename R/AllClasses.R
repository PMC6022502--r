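#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib DomestiScan, .registration = TRUE
NULL

REGION_CLASSES <- c("autosome", "X-PAR", "X-nonPAR")

#' Demographic model for neutral coalescent simulation
#'
#' Describes the populations and (backward-time) events under which neutral
#' genotypes are simulated: named lineages with present-day diploid sizes,
#' ordered size changes, lineage merges (forward-time splits) and migration
#' pulses, a per-site per-generation mutation rate, a generation time in
#' years and a uniform recombination rate (or a genetic map).
#'
#' @slot populations data.frame with columns `name`, `size` (diploid size at
#'   time 0).
#' @slot events data.frame with columns `time` (generations before present,
#'   > 0), `type` (`"size"`, `"merge"` or `"pulse"`), `pop`, `dest`, `value`.
#'   For `"size"`, `value` is the new diploid size of `pop` looking further
#'   into the past; for `"merge"`, lineages of `pop` move into `dest`; for
#'   `"pulse"`, each lineage of `pop` moves to `dest` with probability
#'   `value`.
#' @slot mutationRate per-site per-generation mutation rate.
#' @slot generationTime generation time in years (time conversions only).
#' @slot recombRate uniform recombination rate in Morgans per bp.
#' @slot geneticMap data.frame (`chrom`, `pos`, `morgans`) or NULL.
#'
#' @export
setClass("DemographicModel",
    representation(populations = "data.frame", events = "data.frame",
                   mutationRate = "numeric", generationTime = "numeric",
                   recombRate = "numeric", geneticMap = "ANY"),
    prototype(generationTime = 3, recombRate = 1e-8, geneticMap = NULL))

setValidity("DemographicModel", function(object) {
    msg <- character()
    pops <- object@populations
    if (!all(c("name", "size") %in% names(pops)))
        msg <- c(msg, "populations needs 'name' and 'size' columns")
    else {
        if (anyDuplicated(pops$name)) msg <- c(msg, "duplicated population names")
        if (any(pops$size <= 0)) msg <- c(msg, "all population sizes must be > 0")
    }
    ev <- object@events
    if (nrow(ev)) {
        if (!all(c("time", "type", "pop", "dest", "value") %in% names(ev)))
            msg <- c(msg, "events needs time/type/pop/dest/value columns")
        else {
            if (any(ev$time <= 0)) msg <- c(msg, "event times must be > 0 generations")
            if (is.unsorted(ev$time)) msg <- c(msg, "event times must be ordered into the past")
            if (!all(ev$type %in% c("size", "merge", "pulse")))
                msg <- c(msg, "event type must be size/merge/pulse")
            bad <- !(ev$pop %in% pops$name)
            if (any(bad)) msg <- c(msg, "event pop not among populations")
            needDest <- ev$type %in% c("merge", "pulse")
            if (any(needDest & !(ev$dest %in% pops$name)))
                msg <- c(msg, "merge/pulse dest not among populations")
            if (any(ev$type == "size" & ev$value <= 0))
                msg <- c(msg, "size-change values must be > 0")
        }
    }
    if (length(object@mutationRate) != 1L || object@mutationRate <= 0)
        msg <- c(msg, "mutationRate must be a single positive number")
    if (object@generationTime <= 0) msg <- c(msg, "generationTime must be > 0")
    if (length(msg)) msg else TRUE
})

#' Filtered biallelic SNP genotypes with a sample panel
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding one assay
#' `"GT"`: the count of alternate alleles carried by each sample at each
#' site (0/1/2 for diploid calls, 0/1 for hemizygous male X-nonPAR calls,
#' NA for missing). `rowRanges()` carries `ref`, `alt` and `regionClass`
#' (`"autosome"`, `"X-PAR"` or `"X-nonPAR"`); `colData()` carries the sample
#' panel (`population`, `sex`).
#'
#' @export
setClass("VariantTable", contains = "RangedSummarizedExperiment")

setValidity("VariantTable", function(object) {
    msg <- character()
    if (!"GT" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'GT' is required")
    rd <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
    for (col in c("ref", "alt", "regionClass"))
        if (!col %in% names(rd)) msg <- c(msg, paste0("rowRanges needs '", col, "'"))
    if ("regionClass" %in% names(rd) &&
        !all(rd$regionClass %in% REGION_CLASSES))
        msg <- c(msg, "regionClass must be autosome/X-PAR/X-nonPAR")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("population", "sex"))
        if (!col %in% names(cd)) msg <- c(msg, paste0("colData needs '", col, "'"))
    if ("population" %in% names(cd) &&
        !all(cd$population %in% c("dog", "wolf", "ancient")))
        msg <- c(msg, "population must be dog/wolf/ancient")
    if (length(msg)) msg else TRUE
})

#' Windowed read-depth profiles
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] of per-window,
#' per-sample sequencing depth. Assay `"depth"` is raw windowed depth; GC
#' correction adds assay `"corrected"`. `rowRanges()` carries the window GC
#' fraction (`gc`), a `control` flag and `regionClass`.
#'
#' @export
setClass("DepthProfiles", contains = "RangedSummarizedExperiment")

setValidity("DepthProfiles", function(object) {
    msg <- character()
    if (!"depth" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'depth' is required")
    rd <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
    if (!"gc" %in% names(rd)) msg <- c(msg, "rowRanges needs 'gc'")
    else if (any(rd$gc < 0 | rd$gc > 1, na.rm = TRUE))
        msg <- c(msg, "gc must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Per-window, per-sample copy-number estimates
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with assay `"CN"`
#' (continuous copy number, control windows averaging ~2) and `regionClass`
#' on the rows; `colData()` carries the sample panel.
#'
#' @export
setClass("CopyNumberTable", contains = "RangedSummarizedExperiment")

setValidity("CopyNumberTable", function(object) {
    msg <- character()
    if (!"CN" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'CN' is required")
    rd <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
    if (!"regionClass" %in% names(rd)) msg <- c(msg, "rowRanges needs 'regionClass'")
    if (length(msg)) msg else TRUE
})

#' Synthetic dog/wolf cohort with planted truth
#'
#' Bundles the simulated modern genotypes, reserved ancient haplotypes, the
#' planted sweep and copy-number truth, and (optionally) generated depth
#' tracks and ancient genotypes.
#'
#' @slot variants [VariantTable] of the modern (dog + wolf) samples.
#' @slot sweeps GRanges of planted sweeps (may be empty).
#' @slot cnvs GRanges of planted copy-number differences (may be empty).
#' @slot ancientHaplotypes 0/1 matrix (sites x ancient chromosomes) of the
#'   neutral, pre-sweep ancient haplotypes reserved at simulation time.
#' @slot ancientGenotypes alt-dosage matrix (sites x ancient samples) after
#'   the carrier policy has been applied, or NULL before
#'   [generateAncientSamples()] is called.
#' @slot sweepHaplotypes per-sweep list with the swept haplotype and a
#'   pre-sweep alternative haplotype over the sweep's site indices.
#' @slot depth [DepthProfiles] or NULL.
#' @export
setClass("SyntheticCohort",
    representation(variants = "VariantTable", sweeps = "GRanges",
                   cnvs = "GRanges", ancientHaplotypes = "matrix",
                   ancientGenotypes = "ANY", sweepHaplotypes = "list",
                   depth = "ANY"),
    prototype(ancientGenotypes = NULL, depth = NULL))

#' Simulation-calibrated significance threshold
#'
#' @slot statistic statistic name ("fst", "hp", "xpclr", ...).
#' @slot q percentile (0-100) at which the threshold was taken.
#' @slot threshold the calibrated value.
#' @slot nReplicates number of neutral replicates pooled.
#' @slot values pooled per-window statistic values across replicates.
#' @slot perReplicate integer vector of window counts per replicate.
#' @slot metadata list (genetic-map source, window sizes, ...).
#' @export
setClass("CalibrationResult",
    representation(statistic = "character", q = "numeric",
                   threshold = "numeric", nReplicates = "integer",
                   values = "numeric", perReplicate = "integer",
                   metadata = "list"))

setValidity("CalibrationResult", function(object) {
    msg <- character()
    if (object@q < 0 || object@q > 100) msg <- c(msg, "q must be in [0,100]")
    if (length(object@values) &&
        !isTRUE(all.equal(object@threshold,
                          stats::quantile(object@values, object@q / 100,
                                          type = 7, names = FALSE))))
        msg <- c(msg, "threshold is not reproducible from stored values")
    if (length(msg)) msg else TRUE
})
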