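#' Genetic distances from a map, in Morgans
#'
#' Linear interpolation between map anchors; positions beyond the map ends
#' are extrapolated linearly using the terminal segment's rate. With no
#' map, a uniform rate is applied.
#'
#' @param positions physical positions (bp) on one chromosome.
#' @param map data.frame(`pos`, `morgans`) with `pos` ascending and
#'   `morgans` non-decreasing, or NULL for the uniform fallback.
#' @param rate uniform recombination rate in Morgans per bp (1e-8 = 1
#'   cM/Mb).
#' @return numeric vector of cumulative genetic positions (Morgans).
#' @export
geneticDistances <- function(positions, map = NULL, rate = 1e-8) {
    if (is.null(map)) return(positions * rate)
    if (is.unsorted(map$pos, strictly = TRUE)) stop("unsorted genetic map")
    if (is.unsorted(map$morgans)) stop("genetic map distances must be non-decreasing")
    n <- nrow(map)
    if (n == 1) return(map$morgans + (positions - map$pos) * rate)
    out <- stats::approx(map$pos, map$morgans, xout = positions,
                         rule = 1)$y
    lowRate <- (map$morgans[2] - map$morgans[1]) / (map$pos[2] - map$pos[1])
    hiRate <- (map$morgans[n] - map$morgans[n - 1]) /
        (map$pos[n] - map$pos[n - 1])
    low <- positions < map$pos[1]
    hi <- positions > map$pos[n]
    out[low] <- map$morgans[1] + (positions[low] - map$pos[1]) * lowRate
    out[hi] <- map$morgans[n] + (positions[hi] - map$pos[n]) * hiRate
    out
}

#' XP-CLR runtime configuration
#'
#' Runtime parameters of the cross-population composite likelihood ratio
#' scan. The selection grid is a set of sweep scales s (Morgans): a
#' lineage at genetic distance r from the swept site escapes the sweep
#' with probability `1 - exp(-r/s)`; s = 0 denotes the neutral model and
#' must be included. The drift variance omega is estimated genome-wide
#' from dog-wolf frequency differentiation when not supplied.
#'
#' @param gridSpacing grid point spacing (bp), default 2 kb.
#' @param snpWindow SNP window around each grid point (bp), default 50 kb.
#' @param sGrid selection-scale grid (Morgans), including 0.
#' @param omega drift variance coefficient, or NULL to estimate.
#' @param maxSnps maximum SNPs per grid window (0 = unbounded).
#' @param nQuad Gauss-Legendre quadrature nodes for the frequency
#'   integral.
#' @return list of class "XpclrConfig".
#' @export
xpclrConfig <- function(gridSpacing = 2000, snpWindow = 50000,
                        sGrid = c(0, 1e-4, 3e-4, 1e-3, 3e-3, 1e-2),
                        omega = NULL, maxSnps = 0L, nQuad = 16L) {
    stopifnot(gridSpacing > 0, snpWindow > 0, 0 %in% sGrid)
    structure(list(gridSpacing = gridSpacing, snpWindow = snpWindow,
                   sGrid = sort(unique(sGrid)), omega = omega,
                   maxSnps = as.integer(maxSnps), nQuad = as.integer(nQuad)),
              class = "XpclrConfig")
}

#' Genome-wide drift variance estimate for XP-CLR
#'
#' Method-of-moments estimate of the Brownian drift variance coefficient:
#' the mean of `(p1 - p2)^2 / (p2 (1 - p2))` over SNPs, with the reference
#' frequency clamped away from 0 and 1. Includes binomial sampling noise,
#' making the neutral null slightly conservative.
#'
#' @param freqs data.frame from [alleleFrequencies()].
#' @return positive scalar.
#' @export
estimateOmega <- function(freqs) {
    n2 <- 2 * freqs$nWolf
    eps <- 1 / (n2 + 1)
    p2 <- pmin(pmax(freqs$pWolf, eps), 1 - eps)
    max(mean((freqs$pDog - p2)^2 / (p2 * (1 - p2))), 1e-4)
}

#' Score the XP-CLR grid
#'
#' For each grid point (every `gridSpacing` bp), maximises the composite
#' log-likelihood of the dog allele counts at the SNPs within
#' `snpWindow/2` bp over the selection grid and reports
#' `2 * (max logL - neutral logL)` (>= 0). Wolves are the reference
#' population. Grid points with no usable SNP are flagged failed
#' (`score = NA`).
#'
#' @param freqs data.frame from [alleleFrequencies()].
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param config an [xpclrConfig()].
#' @param map optional genetic map data.frame(`chrom`, `pos`, `morgans`);
#'   uniform `rate` used otherwise.
#' @param rate uniform recombination rate, Morgans/bp.
#' @return GRanges of width-1 grid points with `score` and `nSnps`.
#' @export
xpclrScoreGrid <- function(freqs, chromLengths, config = xpclrConfig(),
                           map = NULL, rate = 1e-8) {
    omega <- config$omega
    if (is.null(omega)) omega <- estimateOmega(freqs)
    gl <- pracma::gaussLegendre(config$nQuad, 0, 1)
    out <- list()
    for (ch in names(chromLengths)) {
        f <- freqs[freqs$chrom == ch, , drop = FALSE]
        centres <- seq(config$gridSpacing / 2, chromLengths[[ch]],
                       by = config$gridSpacing)
        if (!nrow(f)) {
            gr <- GRanges(ch, IRanges(round(centres), width = 1))
            mcols(gr) <- DataFrame(score = NA_real_, nSnps = 0L)
            out[[ch]] <- gr
            next
        }
        f <- f[order(f$pos), , drop = FALSE]
        n1chrom <- as.integer(round(2 * max(f$nDog)))
        k1 <- as.integer(round(f$pDog * 2 * f$nDog))
        eps <- 1 / (2 * f$nWolf + 1)
        p2 <- pmin(pmax(f$pWolf, eps), 1 - eps)
        chMap <- if (!is.null(map)) map[map$chrom == ch, , drop = FALSE] else NULL
        if (!is.null(chMap) && !nrow(chMap)) chMap <- NULL
        posM <- geneticDistances(f$pos, chMap, rate)
        gridM <- geneticDistances(centres, chMap, rate)
        m <- .xpclrGridCpp(k1, n1chrom, p2, as.numeric(f$pos), posM,
                           as.numeric(centres), gridM, config$sGrid,
                           omega, gl$x, gl$w, config$snpWindow / 2,
                           config$maxSnps)
        gr <- GRanges(ch, IRanges(round(centres), width = 1))
        mcols(gr) <- DataFrame(score = m[, 1], nSnps = as.integer(m[, 2]))
        out[[ch]] <- gr
    }
    grid <- suppressWarnings(do.call(c, unname(out)))
    GenomeInfoDb::seqlengths(grid) <-
        chromLengths[GenomeInfoDb::seqlevels(grid)]
    S4Vectors::metadata(grid)$omega <- omega
    grid
}

#' Average grid scores in sliding windows
#'
#' Window value is the mean of the passing (non-failed) grid scores
#' inside; windows with fewer than `minGrids` passing grids carry no value
#' (`pass_support = FALSE`).
#'
#' @param grid GRanges from [xpclrScoreGrid()].
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param win,step window and step sizes (bp), defaults 25 kb / 10 kb.
#' @param minGrids minimum passing grids per window (default 5).
#' @return GRanges of windows with `value`, `support`, `pass_support`,
#'   `regionClass`.
#' @export
averageGridWindows <- function(grid, chromLengths, win = 25000,
                               step = 10000, minGrids = 5) {
    windows <- makeWindows(chromLengths, win, step)
    ok <- !is.na(mcols(grid)$score)
    hit <- findOverlaps(grid[ok], windows)
    w <- S4Vectors::subjectHits(hit)
    sc <- mcols(grid)$score[ok][S4Vectors::queryHits(hit)]
    mn <- tapply(sc, w, mean)
    n <- tapply(sc, w, length)
    value <- rep(NA_real_, length(windows))
    support <- integer(length(windows))
    i <- as.integer(names(mn))
    value[i] <- as.numeric(mn)
    support[i] <- as.integer(n)
    mcols(windows)$value <- ifelse(support >= minGrids, value, NA_real_)
    mcols(windows)$support <- support
    mcols(windows)$pass_support <- support >= minGrids
    mcols(windows)$regionClass <- regionClassOf(windows)
    windows
}

#' Call XP-CLR candidate regions
#'
#' Windows pass when the averaged score strictly exceeds the calibrated
#' threshold AND dog Hp is below its threshold AND deltaHp is at or below
#' its threshold; passing windows within `maxGap` bp are merged.
#'
#' @param windows GRanges from [averageGridWindows()] carrying `hp` and
#'   `deltaHp` columns (see [deltaHp()]).
#' @param threshold calibrated XP-CLR threshold.
#' @param hpThreshold,dhpThreshold Hp / deltaHp thresholds.
#' @param maxGap merge distance in bp (default 50 kb).
#' @return GRanges of merged candidate regions.
#' @export
xpclrCandidates <- function(windows, threshold, hpThreshold, dhpThreshold,
                            maxGap = 50000) {
    if (is.null(threshold) || is.na(threshold))
        stop("a calibrated XP-CLR threshold is required")
    windows <- applyHpFilters(windows, hpThreshold, dhpThreshold)
    v <- mcols(windows)$value
    pass <- !is.na(v) & v > threshold & mcols(windows)$pass_hp_all
    mergeRegions(windows[pass], maxGap = maxGap)
}

#' Read a genetic map TSV
#'
#' Expects columns `chrom`, `pos` (bp) and either `morgans` or `cM`.
#' @param path TSV file with a header.
#' @return data.frame with chrom, pos, morgans.
#' @export
readGeneticMap <- function(path) {
    m <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (is.null(m$morgans)) {
        if (is.null(m$cM)) stop("need a 'morgans' or 'cM' column")
        m$morgans <- m$cM / 100
    }
    m[c("chrom", "pos", "morgans")]
}
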