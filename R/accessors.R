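#' @importFrom SummarizedExperiment assay assayNames rowRanges colData
#'   SummarizedExperiment assays assays<- assay<-
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#'   findOverlaps reduce gaps
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics sort
NULL

#' Construct a VariantTable from a genotype dosage matrix
#'
#' @param gt integer matrix, sites x samples, of alternate-allele counts
#'   (0/1/2; 0/1 in male X-nonPAR; NA missing).
#' @param sites `GRanges` of width-1 SNP positions, same length as
#'   `nrow(gt)`, with optional `ref`/`alt` metadata columns (defaulting to
#'   "A"/"G").
#' @param panel data.frame with columns `sample`, `population`
#'   (dog/wolf/ancient) and `sex` (male/female/unknown), one row per column
#'   of `gt`.
#' @param parIntervals optional `GRanges` of X pseudoautosomal regions used
#'   to classify X sites; X sites outside them are X-nonPAR.
#' @return A [VariantTable-class].
#' @export
VariantTable <- function(gt, sites, panel, parIntervals = NULL) {
    stopifnot(is.matrix(gt), length(sites) == nrow(gt),
              nrow(panel) == ncol(gt))
    panel <- validatePanel(panel)
    mc <- mcols(sites)
    if (is.null(mc$ref)) mc$ref <- rep("A", length(sites))
    if (is.null(mc$alt)) mc$alt <- rep("G", length(sites))
    if (is.null(mc$regionClass))
        mc$regionClass <- regionClassOf(sites, parIntervals)
    mcols(sites) <- mc
    colnames(gt) <- panel$sample
    cd <- DataFrame(population = panel$population, sex = panel$sex,
                    row.names = panel$sample)
    se <- SummarizedExperiment(assays = list(GT = gt), rowRanges = sites,
                               colData = cd)
    methods::new("VariantTable", se)
}

#' Classify sites as autosome / X-PAR / X-nonPAR
#'
#' Chromosomes named "chrX" or "X" are X; X positions inside the supplied
#' pseudoautosomal intervals are "X-PAR", the rest "X-nonPAR"; everything
#' else is "autosome".
#' @param gr GRanges of positions.
#' @param parIntervals GRanges of PAR intervals or NULL.
#' @return character vector of region classes.
#' @export
regionClassOf <- function(gr, parIntervals = NULL) {
    cls <- rep("autosome", length(gr))
    isX <- as.character(seqnames(gr)) %in% c("chrX", "X")
    if (any(isX)) {
        cls[isX] <- "X-nonPAR"
        if (!is.null(parIntervals) && length(parIntervals)) {
            hit <- IRanges::overlapsAny(gr, parIntervals)
            cls[isX & hit] <- "X-PAR"
        }
    }
    cls
}

validatePanel <- function(panel) {
    panel <- as.data.frame(panel)
    need <- c("sample", "population", "sex")
    if (!all(need %in% names(panel)))
        stop("panel needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(panel$sample)) stop("duplicated sample IDs in panel")
    if (!all(panel$population %in% c("dog", "wolf", "ancient")))
        stop("panel population must be one of dog/wolf/ancient")
    if (!all(panel$sex %in% c("male", "female", "unknown")))
        stop("panel sex must be one of male/female/unknown")
    panel
}

#' Read a sample panel TSV (sample, population, sex)
#' @param path TSV file with a header.
#' @return validated data.frame.
#' @export
readPanel <- function(path) {
    validatePanel(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' Extract the genotype dosage matrix
#' @param x A [VariantTable-class].
#' @return integer matrix sites x samples.
#' @export
genotypes <- function(x) assay(x, "GT")

#' Extract the sample panel of a VariantTable or CopyNumberTable
#' @param x object with panel columns in `colData()`.
#' @return data.frame with sample/population/sex.
#' @export
samplePanel <- function(x) {
    cd <- colData(x)
    data.frame(sample = rownames(cd), population = cd$population,
               sex = cd$sex, stringsAsFactors = FALSE)
}

#' Per-cell chromosome copy (ploidy) of a VariantTable
#'
#' 2 everywhere except male samples at X-nonPAR sites, which contribute a
#' single chromosome.
#' @param x A [VariantTable-class].
#' @return integer matrix sites x samples.
#' @export
ploidyMatrix <- function(x) {
    p <- matrix(2L, nrow(x), ncol(x), dimnames = dimnames(assay(x, "GT")))
    male <- colData(x)$sex == "male"
    nonpar <- rowRanges(x)$regionClass == "X-nonPAR"
    if (any(male) && any(nonpar)) p[nonpar, male] <- 1L
    p
}

setMethod("show", "VariantTable", function(object) {
    cd <- colData(object)
    cat("VariantTable:", nrow(object), "biallelic SNPs x",
        ncol(object), "samples\n")
    cat("  populations:", paste(sprintf("%s=%d", names(table(cd$population)),
        table(cd$population)), collapse = ", "), "\n")
    cat("  region classes:", paste(sprintf("%s=%d",
        names(table(rowRanges(object)$regionClass)),
        table(rowRanges(object)$regionClass)), collapse = ", "), "\n")
})

setMethod("show", "DemographicModel", function(object) {
    cat("DemographicModel:", nrow(object@populations), "lineage(s),",
        nrow(object@events), "event(s)\n")
    cat("  mutation rate:", object@mutationRate, "/site/generation;",
        "generation time:", object@generationTime, "y\n")
    sz <- sprintf("%s (2N=%g)", object@populations$name,
                  2 * object@populations$size)
    cat("  lineages:", paste(sz, collapse = ", "), "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:", nrow(object@variants), "SNPs,",
        ncol(object@variants), "modern samples,",
        ncol(object@ancientHaplotypes) / 2, "reserved ancient sample(s)\n")
    cat("  planted sweeps:", length(object@sweeps),
        "| planted CNVs:", length(object@cnvs),
        "| ancient genotypes:",
        if (is.null(object@ancientGenotypes)) "not drawn" else "drawn", "\n")
})

setMethod("show", "CalibrationResult", function(object) {
    cat(sprintf("CalibrationResult: %s q=%g -> threshold %.6g (%d replicates, %d pooled windows)\n",
        object@statistic, object@q, object@threshold, object@nReplicates,
        length(object@values)))
})

#' Accessors for SyntheticCohort and CalibrationResult
#' @param x the object.
#' @return the corresponding component.
#' @rdname cohort-accessors
#' @export
cohortVariants <- function(x) x@variants
#' @rdname cohort-accessors
#' @export
cohortSweeps <- function(x) x@sweeps
#' @rdname cohort-accessors
#' @export
cohortCnvs <- function(x) x@cnvs
#' @rdname cohort-accessors
#' @export
cohortDepth <- function(x) x@depth
#' @rdname cohort-accessors
#' @export
ancientGenotypes <- function(x) x@ancientGenotypes
#' @rdname cohort-accessors
#' @export
calibratedThreshold <- function(x) x@threshold
#' @rdname cohort-accessors
#' @export
calibrationValues <- function(x) x@values
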