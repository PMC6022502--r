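#' Re-evaluate previously published loci under the filter cascade
#'
#' For each externally published locus, takes the maximum windowed F_ST
#' over the scan windows overlapping it by at least one bp, reads the Hp
#' and deltaHp of that same maximal window, and applies the three
#' thresholds: the locus passes only when its best window exceeds the
#' F_ST threshold, its Hp is below the Hp threshold and its deltaHp is at
#' or below the deltaHp threshold. Loci overlapping no scanned window are
#' flagged `no_data`.
#'
#' @param loci GRanges of published loci, optionally with a `source`
#'   column.
#' @param fstWindows GRanges from [windowedFst()] additionally carrying
#'   `hp` and `deltaHp` columns (see [deltaHp()]).
#' @param fstThreshold,hpThreshold,dhpThreshold the scan thresholds.
#' @return data.frame, one row per locus, with the extracted statistics
#'   and per-filter pass flags.
#' @export
refilterLoci <- function(loci, fstWindows, fstThreshold, hpThreshold,
                         dhpThreshold) {
    if (any(width(loci) <= 0)) stop("zero-width locus")
    hit <- findOverlaps(loci, fstWindows, minoverlap = 1)
    src <- mcols(loci)$source
    if (is.null(src)) src <- rep(NA_character_, length(loci))
    out <- data.frame(
        source = src, chrom = as.character(seqnames(loci)),
        start = start(loci) - 1, end = end(loci),
        maxFst = NA_real_, hp = NA_real_, deltaHp = NA_real_,
        pass_fst = NA, pass_hp = NA, pass_dhp = NA, pass = NA,
        status = "no_data", stringsAsFactors = FALSE)
    v <- mcols(fstWindows)$value
    for (i in seq_along(loci)) {
        w <- S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == i]
        w <- w[!is.na(v[w])]
        if (!length(w)) next
        best <- w[which.max(v[w])]
        out$maxFst[i] <- v[best]
        out$hp[i] <- mcols(fstWindows)$hp[best]
        out$deltaHp[i] <- mcols(fstWindows)$deltaHp[best]
        out$pass_fst[i] <- out$maxFst[i] > fstThreshold
        out$pass_hp[i] <- !is.na(out$hp[i]) && out$hp[i] < hpThreshold
        out$pass_dhp[i] <- !is.na(out$deltaHp[i]) &&
            out$deltaHp[i] <= dhpThreshold
        out$pass[i] <- out$pass_fst[i] && out$pass_hp[i] && out$pass_dhp[i]
        out$status[i] <- "scored"
    }
    out
}
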