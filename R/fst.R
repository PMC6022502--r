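#' Per-site Hudson F_ST
#'
#' Hudson-estimator fixation index for one or more biallelic sites:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`, with `n` the number of individuals per
#' population. Sites at which both populations are fixed for the same
#' allele have a zero denominator and are flagged non-computable
#' (`fst = NA`) rather than assigned a value.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 numbers of individuals (>= 2); for X-nonPAR sites use the
#'   effective chromosome count divided by two.
#' @return data.frame with `numerator`, `denominator`, `fst`.
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
    stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1),
              all(n1 >= 2), all(n2 >= 2))
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- ifelse(den > 0, num / den, NA_real_)
    data.frame(numerator = ifelse(den > 0, num, NA_real_),
               denominator = ifelse(den > 0, den, NA_real_), fst = fst)
}

#' Per-site F_ST table from allele frequencies
#'
#' @param freqs data.frame from [alleleFrequencies()].
#' @return `freqs` with `numerator`, `denominator` and `fst` columns; sites
#'   with an undefined estimator (both populations fixed for the same
#'   allele) are excluded.
#' @export
siteFst <- function(freqs) {
    f <- hudsonFst(freqs$pDog, freqs$nDog, freqs$pWolf, freqs$nWolf)
    out <- cbind(freqs, f)
    out[!is.na(out$fst), , drop = FALSE]
}

#' Windowed ratio-of-averages F_ST
#'
#' The window statistic is the ratio of the mean per-site numerator to the
#' mean per-site denominator over the SNPs falling in the window (with
#' sliding windows a SNP contributes to every window containing it).
#' Windows with fewer than `minSnps` SNPs are flagged unusable
#' (`value = NA`, `pass_support = FALSE`).
#'
#' @param sites data.frame from [siteFst()].
#' @param windows GRanges from [makeWindows()].
#' @param minSnps minimum SNPs per window (default 10).
#' @return `windows` with `value`, `support`, `pass_support` and
#'   `regionClass` metadata columns.
#' @export
windowedFst <- function(sites, windows, minSnps = 10) {
    gr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1))
    hit <- findOverlaps(gr, windows)
    w <- S4Vectors::subjectHits(hit)
    s <- S4Vectors::queryHits(hit)
    num <- tapply(sites$numerator[s], w, sum)
    den <- tapply(sites$denominator[s], w, sum)
    n <- tapply(s, w, length)
    value <- rep(NA_real_, length(windows))
    support <- integer(length(windows))
    i <- as.integer(names(num))
    value[i] <- as.numeric(num) / as.numeric(den)
    support[i] <- as.integer(n)
    mcols(windows)$value <- ifelse(support >= minSnps, value, NA_real_)
    mcols(windows)$support <- support
    mcols(windows)$pass_support <- support >= minSnps
    if (is.null(mcols(windows)$regionClass)) {
        rc <- tapply(as.character(sites$regionClass)[s], w, function(x) x[1])
        cls <- rep("autosome", length(windows))
        cls[as.integer(names(rc))] <- as.character(rc)
        mcols(windows)$regionClass <- cls
    }
    windows
}

#' Call F_ST outlier windows and merge them into candidate regions
#'
#' In `"empirical"` mode windows are kept at Z >= 5 (autosome and X-PAR)
#' or Z >= 3 (X-nonPAR) after [zTransform()]. In `"calibrated"` mode
#' windows are kept when the raw statistic strictly exceeds a
#' simulation-derived threshold. Passing windows are merged with zero
#' allowed gap (overlapping or book-ended windows join).
#'
#' @param windows GRanges from [windowedFst()]; Z-transformed already in
#'   empirical mode (otherwise it is applied here).
#' @param mode "empirical" or "calibrated".
#' @param threshold calibrated threshold (required in calibrated mode).
#' @param zAuto,zNonPar empirical Z cutoffs.
#' @return GRanges of merged candidate regions.
#' @export
fstOutlierScan <- function(windows, mode = c("empirical", "calibrated"),
                           threshold = NULL, zAuto = 5, zNonPar = 3) {
    mode <- match.arg(mode)
    if (mode == "calibrated") {
        if (is.null(threshold)) stop("calibrated mode requires a threshold")
        pass <- !is.na(mcols(windows)$value) & mcols(windows)$value > threshold
    } else {
        if (is.null(mcols(windows)$zscore)) windows <- zTransform(windows)
        z <- mcols(windows)$zscore
        rc <- mcols(windows)$regionClass
        if (is.null(rc)) rc <- rep("autosome", length(windows))
        cut <- ifelse(rc == "X-nonPAR", zNonPar, zAuto)
        pass <- !is.na(z) & z >= cut
    }
    mergeRegions(windows[pass], maxGap = 0)
}
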