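#' @importFrom VariantAnnotation readVcf writeVcf geno isSNV VCF VCFHeader
#'   ref alt header
#' @importFrom Biostrings DNAStringSet DNAStringSetList
NULL

# "0/0", "0|1", "1", "./." ... -> alt-allele dosage (NA if missing)
gtStringToDosage <- function(gt) {
    clean <- gsub("\\|", "/", gt)
    d <- rep(NA_integer_, length(gt))
    d[clean == "0/0"] <- 0L
    d[clean %in% c("0/1", "1/0")] <- 1L
    d[clean == "1/1"] <- 2L
    d[clean == "0"] <- 0L
    d[clean == "1"] <- 1L
    matrix(d, nrow(gt), ncol(gt), dimnames = dimnames(gt))
}

#' Load and filter variants from a VCF
#'
#' Applies the cohort site filters: keeps biallelic SNPs only, drops sites
#' with a missing genotype in any sample, drops SNPs within 5 bp of an
#' indel present in the same VCF, and drops X-nonPAR sites at which any
#' male sample is heterozygous. Male X-nonPAR genotypes are stored as
#' single-chromosome dosages. Region class (autosome / X-PAR / X-nonPAR)
#' is annotated from the PAR intervals.
#'
#' If the VCF contains no indel records the indel-proximity filter is a
#' no-op (a warning is emitted, since indels may have been removed
#' upstream).
#'
#' @param vcfPath VCF 4.x file.
#' @param panel sample panel data.frame (see [readPanel()]); must cover all
#'   VCF samples.
#' @param parIntervals GRanges of X pseudoautosomal regions, or NULL.
#' @param indelWindow exclusion distance around indels in bp.
#' @return A [VariantTable-class].
#' @export
loadVariants <- function(vcfPath, panel, parIntervals = NULL,
                         indelWindow = 5) {
    panel <- validatePanel(panel)
    vcf <- tryCatch(readVcf(vcfPath),
                    error = function(e) stop("malformed VCF '", vcfPath,
                                             "': ", conditionMessage(e)))
    vcfSamples <- colnames(vcf)
    missing <- setdiff(vcfSamples, panel$sample)
    if (length(missing))
        stop("VCF sample(s) not in panel: ", paste(missing, collapse = ", "))
    panel <- panel[match(vcfSamples, panel$sample), , drop = FALSE]

    rr <- rowRanges(vcf)
    altList <- alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altList)
    snv <- isSNV(vcf, singleAltOnly = FALSE)
    indels <- rr[!snv & nAlt >= 1]
    keep <- snv & nAlt == 1
    if (length(indels)) {
        nearIndel <- IRanges::overlapsAny(
            rr, GenomicRanges::resize(indels,
                width = GenomicRanges::width(indels) + 2 * indelWindow,
                fix = "center"))
        keep <- keep & !nearIndel
    } else {
        warning("no indel records in VCF; indel-proximity filter is a no-op")
    }
    vcf <- vcf[keep]
    if (!nrow(vcf)) stop("no biallelic SNPs left after filtering")

    gt <- gtStringToDosage(geno(vcf)$GT)
    rownames(gt) <- NULL
    complete <- rowSums(is.na(gt)) == 0
    vcf <- vcf[complete]
    gt <- gt[complete, , drop = FALSE]

    sites <- granges(rowRanges(vcf))
    names(sites) <- NULL
    mcols(sites) <- DataFrame(
        ref = as.character(ref(vcf)),
        alt = as.character(unlist(alt(vcf))),
        regionClass = regionClassOf(sites, parIntervals))

    # X-nonPAR: drop male-heterozygous sites, then recode males as haploid
    male <- panel$sex == "male"
    nonpar <- mcols(sites)$regionClass == "X-nonPAR"
    if (any(nonpar) && any(male)) {
        het <- gt[, male, drop = FALSE] == 1L
        bad <- nonpar & rowSums(het) > 0
        sites <- sites[!bad]
        gt <- gt[!bad, , drop = FALSE]
        nonpar <- nonpar[!bad]
        gt[nonpar, male] <- gt[nonpar, male, drop = FALSE] %/% 2L
    }
    VariantTable(gt, sites, panel)
}

#' Minor-allele-count filter
#'
#' Drops sites whose minor-allele count across all modern (dog + wolf)
#' chromosomes is below `minMinorCount`. With 43 dogs and 10 wolves there
#' are 106 autosomal chromosomes, so the default removes sites with minor
#' allele frequency below 3/106 = 0.028.
#'
#' @param x A [VariantTable-class].
#' @param minMinorCount minimum minor-allele count (strictly-below drops).
#' @return the filtered [VariantTable-class].
#' @export
mafFilter <- function(x, minMinorCount = 3) {
    gt <- genotypes(x)
    modern <- colData(x)$population %in% c("dog", "wolf")
    if (anyNA(gt[, modern]))
        stop("mafFilter requires complete genotypes; run loadVariants first")
    pl <- ploidyMatrix(x)
    altC <- rowSums(gt[, modern, drop = FALSE])
    tot <- rowSums(pl[, modern, drop = FALSE])
    if (any(tot > 2 * sum(modern)))
        stop("total alleles at a site exceed 2 x samples")
    minor <- pmin(altC, tot - altC)
    x[minor >= minMinorCount, ]
}

#' The frequency cutoff implied by the minor-allele-count filter
#' @param minMinorCount minimum minor-allele count.
#' @param totalAlleles total chromosomes sampled (2 x modern samples).
#' @return the frequency below which sites are removed.
#' @export
mafCutoff <- function(minMinorCount = 3, totalAlleles = 106) {
    minMinorCount / totalAlleles
}

#' Per-site allele frequencies and dog major/minor counts
#'
#' Computes the alternate-allele frequency separately in dogs (p1) and
#' wolves (p2); males contribute one chromosome at X-nonPAR sites and two
#' elsewhere. Major/minor allele counts are assigned within dogs (ties:
#' the reference allele is major). The effective number of individuals per
#' population (`nDog`, `nWolf`) is the chromosome count divided by two, so
#' X-nonPAR sites carry fractional effective sizes. Ancient samples are
#' excluded throughout.
#'
#' @param x A [VariantTable-class].
#' @return data.frame with chrom, pos, regionClass, pDog, pWolf, nDog,
#'   nWolf, nMAJ, nMIN, majorIsRef.
#' @export
alleleFrequencies <- function(x) {
    cd <- colData(x)
    dog <- cd$population == "dog"
    wolf <- cd$population == "wolf"
    if (!any(dog) || !any(wolf))
        stop("both dog and wolf populations must be non-empty")
    gt <- genotypes(x)
    pl <- ploidyMatrix(x)
    dAlt <- rowSums(gt[, dog, drop = FALSE])
    dTot <- rowSums(pl[, dog, drop = FALSE])
    wAlt <- rowSums(gt[, wolf, drop = FALSE])
    wTot <- rowSums(pl[, wolf, drop = FALSE])
    pDog <- dAlt / dTot
    pWolf <- wAlt / wTot
    # dog major/minor: major = more frequent dog allele; tie -> reference
    altIsMajor <- dAlt > dTot - dAlt
    nMAJ <- ifelse(altIsMajor, dAlt, dTot - dAlt)
    nMIN <- dTot - nMAJ
    rr <- rowRanges(x)
    data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
               regionClass = mcols(rr)$regionClass,
               pDog = pDog, pWolf = pWolf,
               nDog = dTot / 2, nWolf = wTot / 2,
               nMAJ = as.integer(nMAJ), nMIN = as.integer(nMIN),
               majorIsRef = !altIsMajor, stringsAsFactors = FALSE)
}

#' Write a VariantTable to VCF 4.x
#'
#' @param x A [VariantTable-class].
#' @param path output path (".vcf"; a ".gz" suffix compresses).
#' @return the path, invisibly.
#' @export
writeVariantVcf <- function(x, path) {
    gt <- genotypes(x)
    pl <- ploidyMatrix(x)
    chr <- matrix("0/0", nrow(gt), ncol(gt), dimnames = dimnames(gt))
    chr[gt == 1L & pl == 2L] <- "0/1"
    chr[gt == 2L] <- "1/1"
    chr[gt == 0L & pl == 1L] <- "0"
    chr[gt == 1L & pl == 1L] <- "1"
    chr[is.na(gt)] <- "./."
    rr <- granges(rowRanges(x))
    names(rr) <- paste0(seqnames(rr), ":", start(rr))
    fixed <- DataFrame(
        REF = DNAStringSet(rowRanges(x)$ref),
        ALT = DNAStringSetList(as.list(rowRanges(x)$alt)),
        QUAL = rep(NA_real_, nrow(x)),
        FILTER = rep("PASS", nrow(x)))
    # scan a minimal stub so the header object serialises in valid order
    stub <- tempfile(fileext = ".vcf")
    on.exit(unlink(stub))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(gt)),
                       collapse = "\t")), stub)
    hdr <- VariantAnnotation::scanVcfHeader(stub)
    out <- VCF(rowRanges = rr, colData = colData(x),
               exptData = list(header = hdr), fixed = fixed,
               geno = S4Vectors::SimpleList(GT = chr))
    writeVcf(out, path)
    invisible(path)
}

#' Write the panel of a VariantTable as TSV
#' @param panel data.frame sample/population/sex.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writePanel <- function(panel, path) {
    utils::write.table(validatePanel(panel), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
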