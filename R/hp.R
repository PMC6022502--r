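#' Pooled heterozygosity per window
#'
#' Dog pooled heterozygosity `Hp = 2 * S_MAJ * S_MIN / (S_MAJ + S_MIN)^2`,
#' where `S_MAJ` and `S_MIN` sum the per-site dog major- and minor-allele
#' counts over all SNPs in the window. Swept windows approach 0; the
#' maximum (equal sums) is 0.5. Windows containing no SNPs are flagged
#' (`hp = NA`).
#'
#' @param freqs data.frame from [alleleFrequencies()] (needs `nMAJ`,
#'   `nMIN`).
#' @param windows GRanges.
#' @return `windows` with `sumMaj`, `sumMin`, `hp` and `hpSupport`
#'   metadata.
#' @export
windowHp <- function(freqs, windows) {
    gr <- GRanges(freqs$chrom, IRanges(freqs$pos, width = 1))
    hit <- findOverlaps(gr, windows)
    w <- S4Vectors::subjectHits(hit)
    s <- S4Vectors::queryHits(hit)
    sumMaj <- rep(0, length(windows))
    sumMin <- rep(0, length(windows))
    supp <- integer(length(windows))
    tmaj <- tapply(freqs$nMAJ[s], w, sum)
    tmin <- tapply(freqs$nMIN[s], w, sum)
    tn <- tapply(s, w, length)
    i <- as.integer(names(tmaj))
    sumMaj[i] <- as.numeric(tmaj)
    sumMin[i] <- as.numeric(tmin)
    supp[i] <- as.integer(tn)
    tot <- sumMaj + sumMin
    hp <- ifelse(tot > 0, 2 * sumMaj * sumMin / tot^2, NA_real_)
    mcols(windows)$sumMaj <- sumMaj
    mcols(windows)$sumMin <- sumMin
    mcols(windows)$hp <- hp
    mcols(windows)$hpSupport <- supp
    windows
}

# per-site dog major/minor counts after adding ancient chromosomes, with
# the major/minor axes frozen from the modern-dog assignment
ancientAugmentedCounts <- function(freqs, ancientGt) {
    stopifnot(nrow(ancientGt) == nrow(freqs))
    nonNA <- !is.na(ancientGt)
    altCount <- rowSums(ancientGt, na.rm = TRUE)
    chromCount <- 2 * rowSums(nonNA)
    majAdd <- ifelse(freqs$majorIsRef, chromCount - altCount, altCount)
    minAdd <- chromCount - majAdd
    data.frame(nMAJ = freqs$nMAJ + majAdd, nMIN = freqs$nMIN + minAdd,
               hasAncient = chromCount > 0)
}

#' Change in pooled heterozygosity when ancient dogs are added
#'
#' Recomputes the per-site dog major/minor counts after pooling the
#' ancient chromosomes (keeping the modern-dog major/minor assignment
#' fixed), recomputes window Hp, and returns the difference
#' `deltaHp = Hp(with ancient) - Hp(without)`. Ancient samples homozygous
#' for the modern major haplotype drive deltaHp <= 0; a different ancient
#' haplotype drives it positive. Sites with missing ancient calls
#' contribute no ancient chromosomes; windows without any ancient call get
#' `deltaHp = NA`.
#'
#' @param freqs data.frame from [alleleFrequencies()].
#' @param ancientGt alt-dosage matrix (sites x ancient samples, diploid,
#'   NA = missing), rows aligned with `freqs`.
#' @param windows GRanges.
#' @return `windows` with `hp`, `hpWithAncient` and `deltaHp` metadata.
#' @export
deltaHp <- function(freqs, ancientGt, windows) {
    windows <- windowHp(freqs, windows)
    aug <- ancientAugmentedCounts(freqs, ancientGt)
    freqs2 <- freqs
    freqs2$nMAJ <- aug$nMAJ
    freqs2$nMIN <- aug$nMIN
    with <- windowHp(freqs2, GRanges(seqnames(windows),
                                     IRanges(start(windows), end(windows))))
    # windows containing no site with an ancient call carry no information
    grA <- GRanges(freqs$chrom, IRanges(freqs$pos, width = 1))[aug$hasAncient]
    hasA <- IRanges::overlapsAny(windows, grA)
    hpW <- ifelse(hasA, mcols(with)$hp, NA_real_)
    mcols(windows)$hpWithAncient <- hpW
    mcols(windows)$deltaHp <- hpW - mcols(windows)$hp
    windows
}

#' Apply the Hp and delta-Hp candidate filters
#'
#' A window passes when its dog pooled heterozygosity is strictly below
#' the simulation-calibrated threshold AND its deltaHp is at or below the
#' genome-wide percentile threshold (i.e. the ancient samples reinforce
#' the swept haplotype).
#'
#' @param windows GRanges with `hp` and `deltaHp` columns (see
#'   [deltaHp()]).
#' @param hpThreshold Hp cutoff (e.g. the 0.1th percentile of neutral
#'   simulations).
#' @param dhpThreshold deltaHp cutoff; the pipeline derives it as an
#'   upper-tail percentile of the genome-wide observed deltaHp
#'   distribution, so that the 5% of windows where adding the ancients
#'   most increases Hp (ancients on a different haplotype) are removed.
#' @return `windows` with logical `pass_hp`, `pass_dhp` and `pass_hp_all`
#'   flags.
#' @export
applyHpFilters <- function(windows, hpThreshold, dhpThreshold) {
    if (is.null(hpThreshold) || is.null(dhpThreshold) ||
        is.na(hpThreshold) || is.na(dhpThreshold))
        stop("both hpThreshold and dhpThreshold are required")
    hp <- mcols(windows)$hp
    dhp <- mcols(windows)$deltaHp
    if (is.null(hp) || is.null(dhp))
        stop("windows need 'hp' and 'deltaHp' columns (run deltaHp first)")
    mcols(windows)$pass_hp <- !is.na(hp) & hp < hpThreshold
    mcols(windows)$pass_dhp <- !is.na(dhp) & dhp <= dhpThreshold
    mcols(windows)$pass_hp_all <- mcols(windows)$pass_hp &
        mcols(windows)$pass_dhp
    windows
}
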