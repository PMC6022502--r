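#' Sliding windows over chromosomes
#'
#' Windows start at 0, `step`, `2*step`, ... (0-based); only full-size
#' windows are emitted, so a chromosome shorter than `size` yields none.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step step size in bp (`size >= step > 0`; `size == step` tiles).
#' @return GRanges of windows (1-based closed internally; BED writers
#'   convert back to 0-based half-open).
#' @export
makeWindows <- function(chromLengths, size, step = size) {
    if (size <= 0 || step <= 0) stop("size and step must be positive")
    if (size < step) stop("size must be >= step")
    if (is.null(names(chromLengths)))
        names(chromLengths) <- paste0("chr", seq_along(chromLengths))
    grl <- lapply(names(chromLengths), function(ch) {
        len <- chromLengths[[ch]]
        if (len < size) return(GRanges())
        starts <- seq(0, len - size, by = step)
        GRanges(ch, IRanges(starts + 1, width = size))
    })
    win <- suppressWarnings(do.call(c, grl))
    GenomeInfoDb::seqlengths(win) <-
        chromLengths[GenomeInfoDb::seqlevels(win)]
    win
}

#' Z-transform window statistics within region partitions
#'
#' Standardises a window statistic to `(value - mean) / sd` (sample sd,
#' denominator N-1) separately within the autosome+X-PAR partition and the
#' X-nonPAR partition, matching the practice of transforming autosomes and
#' the X separately because of their different drift expectations.
#'
#' @param windows GRanges with the statistic in `mcols()[[valueColumn]]`
#'   and optionally a `regionClass` column ("autosome"/"X-PAR"/"X-nonPAR";
#'   absent means all autosomal).
#' @param valueColumn name of the statistic column.
#' @return `windows` with a `zscore` metadata column (NA where the value
#'   is NA).
#' @export
zTransform <- function(windows, valueColumn = "value") {
    v <- mcols(windows)[[valueColumn]]
    if (is.null(v)) stop("no '", valueColumn, "' column on windows")
    rc <- mcols(windows)$regionClass
    if (is.null(rc)) rc <- rep("autosome", length(windows))
    part <- ifelse(rc == "X-nonPAR", "X-nonPAR", "autosome+PAR")
    z <- rep(NA_real_, length(windows))
    for (p in unique(part)) {
        i <- which(part == p & !is.na(v))
        if (length(i) < 2)
            stop("need >= 2 finite values in partition ", p)
        s <- stats::sd(v[i])
        if (s == 0) stop("zero standard deviation in partition ", p)
        z[i] <- (v[i] - mean(v[i])) / s
    }
    mcols(windows)$zscore <- z
    windows
}

#' Linear-interpolation (type 7) percentile
#'
#' @param values non-empty numeric vector.
#' @param q percentile in [0, 100].
#' @return the q-th percentile; `max(values)` at q = 100, `min(values)` at
#'   q = 0.
#' @export
percentileThreshold <- function(values, q) {
    if (!length(values)) stop("empty values")
    if (q < 0 || q > 100) stop("q must be in [0, 100]")
    stats::quantile(values, q / 100, type = 7, names = FALSE, na.rm = TRUE)
}

#' Merge passing windows into candidate regions
#'
#' Windows whose inter-window gap is at most `maxGap` bp are joined into a
#' single region; `maxGap = 0` merges only overlapping or book-ended
#' windows. Bookkeeping records the peak statistic and the number of
#' member windows.
#'
#' @param windows GRanges of passing windows, with an optional statistic
#'   column named by `valueColumn` used for the peak.
#' @param maxGap maximum allowed gap in bp.
#' @param valueColumn statistic column for peak bookkeeping.
#' @return GRanges of non-overlapping regions with `peak` and `nWindows`.
#' @export
mergeRegions <- function(windows, maxGap = 0, valueColumn = "value") {
    if (!length(windows)) {
        out <- GRanges()
        mcols(out)$peak <- numeric()
        mcols(out)$nWindows <- integer()
        return(out)
    }
    windows <- BiocGenerics::sort(windows)
    merged <- GenomicRanges::reduce(windows, min.gapwidth = maxGap + 1)
    hit <- findOverlaps(windows, merged)
    v <- mcols(windows)[[valueColumn]]
    if (is.null(v)) v <- rep(NA_real_, length(windows))
    peak <- tapply(v[S4Vectors::queryHits(hit)],
                   S4Vectors::subjectHits(hit),
                   function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    n <- tapply(S4Vectors::queryHits(hit), S4Vectors::subjectHits(hit), length)
    mcols(merged)$peak <- as.numeric(peak[as.character(seq_along(merged))])
    mcols(merged)$nWindows <- as.integer(n[as.character(seq_along(merged))])
    merged
}
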