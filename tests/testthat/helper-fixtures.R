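suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
    library(IRanges)
})

# small dog/wolf panel for hand-built tables
makePanel <- function(nDogs = 4, nWolves = 4, sexes = NULL) {
    n <- nDogs + nWolves
    if (is.null(sexes)) sexes <- rep(c("female", "male"), length.out = n)
    data.frame(
        sample = c(sprintf("d%02d", seq_len(nDogs)),
                   sprintf("w%02d", seq_len(nWolves))),
        population = c(rep("dog", nDogs), rep("wolf", nWolves)),
        sex = sexes, stringsAsFactors = FALSE)
}

# VariantTable from a dosage matrix on chr1 at positions 1000, 2000, ...
makeVT <- function(gt, panel, chrom = "chr1", pos = NULL,
                   parIntervals = NULL, chromLen = 1e6) {
    if (is.null(pos)) pos <- 1000 * seq_len(nrow(gt))
    sl <- stats::setNames(chromLen, unique(chrom))
    sites <- GRanges(chrom, IRanges(pos, width = 1), seqlengths = sl)
    VariantTable(gt, sites, panel, parIntervals = parIntervals)
}

# allele-frequency rows crafted directly (for Hp / deltaHp arithmetic)
makeFreqRows <- function(nMAJ, nMIN, pos = 1000 * seq_along(nMAJ),
                         chrom = "chr1", majorIsRef = TRUE) {
    nTot <- nMAJ + nMIN
    data.frame(chrom = chrom, pos = pos, regionClass = "autosome",
               pDog = ifelse(rep(majorIsRef, length(nMAJ)),
                             nMIN / nTot, nMAJ / nTot),
               pWolf = 0.5, nDog = nTot / 2, nWolf = 10,
               nMAJ = nMAJ, nMIN = nMIN,
               majorIsRef = rep(majorIsRef, length(nMAJ)),
               stringsAsFactors = FALSE)
}

# brute-force pooled heterozygosity from per-site counts
bruteHp <- function(nMAJ, nMIN) {
    2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2
}

# a quick neutral frequency table without running the coalescent
randomFreqs <- function(nSites, nDog = 43, nWolf = 10, seed = 1,
                        chrom = "chr1", span = 1e6) {
    set.seed(seed)
    pos <- sort(sample(span, nSites))
    kD <- rbinom(nSites, 2 * nDog, runif(nSites, 0.05, 0.95))
    kW <- rbinom(nSites, 2 * nWolf, runif(nSites, 0.05, 0.95))
    nMAJ <- pmax(kD, 2 * nDog - kD)
    data.frame(chrom = chrom, pos = pos, regionClass = "autosome",
               pDog = kD / (2 * nDog), pWolf = kW / (2 * nWolf),
               nDog = nDog, nWolf = nWolf,
               nMAJ = nMAJ, nMIN = 2 * nDog - nMAJ,
               majorIsRef = kD <= nDog, stringsAsFactors = FALSE)
}

# shared small simulated cohorts (built once per test run)
testModel <- function() twoPopModel()

.cache <- new.env()
cachedNeutralCohort <- function() {
    if (is.null(.cache$neutral)) {
        co <- generateCohort(testModel(), c(chr1 = 4e6), nDogs = 43,
                             nWolves = 10, nAncient = 2, seed = 11)
        .cache$neutral <- generateAncientSamples(co, seed = 12)
    }
    .cache$neutral
}
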