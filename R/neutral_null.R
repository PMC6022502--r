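#' Simulate neutral replicates under a demographic model
#'
#' Runs the block-coalescent simulator with no sweeps, once per replicate
#' with distinct seeds, emulating independent neutral simulations of the
#' cohort (default 43 dogs + 10 wolves).
#'
#' @param model A [DemographicModel-class].
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param reps number of replicates.
#' @param seed base seed; replicate seeds are `seed + 0:(reps-1)` unless
#'   `seeds` is given.
#' @param seeds optional explicit distinct seeds (length `reps`).
#' @param nDogs,nWolves sample sizes.
#' @param blockSize coalescent block length (bp).
#' @return list of [VariantTable-class] objects.
#' @export
simulateNeutral <- function(model, chromLengths, reps = 75, seed = 1,
                            seeds = NULL, nDogs = 43, nWolves = 10,
                            blockSize = 20000) {
    methods::validObject(model)
    if (is.null(seeds)) seeds <- seed + seq_len(reps) - 1L
    if (length(seeds) != reps) stop("need one seed per replicate")
    if (anyDuplicated(seeds)) stop("replicate seeds must be distinct")
    lapply(seeds, function(s)
        cohortVariants(generateCohort(model, chromLengths, sweeps = NULL,
                                      nDogs = nDogs, nWolves = nWolves,
                                      nAncient = 0, seed = s,
                                      blockSize = blockSize)))
}

#' Match a simulated SNP set to the real data
#'
#' Applies the same minor-allele-count rule as the real data, then
#' uniformly thins (seeded) to exactly the real per-chromosome SNP counts.
#'
#' @param sim A [VariantTable-class] from [simulateNeutral()].
#' @param realCounts named integer vector of per-chromosome SNP counts.
#' @param minMinorCount minor-allele-count rule (see [mafFilter()]).
#' @param seed integer seed for the thinning draw.
#' @return the thinned [VariantTable-class].
#' @export
matchRealSnps <- function(sim, realCounts, minMinorCount = 3, seed = 1) {
    sim <- mafFilter(sim, minMinorCount)
    chrom <- as.character(seqnames(rowRanges(sim)))
    set.seed(seed)
    keep <- unlist(lapply(names(realCounts), function(ch) {
        i <- which(chrom == ch)
        need <- realCounts[[ch]]
        if (length(i) < need)
            stop("only ", length(i), " simulated SNPs on ", ch, " after the ",
                 "MAF filter but ", need, " required; simulate a longer ",
                 "chromosome or more replicates")
        sort(sample(i, need))
    }))
    sim[keep, ]
}

#' Calibrate a percentile threshold from neutral simulations
#'
#' Applies a scan function to every simulated replicate with the same
#' parameters as the real scan, pools all finite window values, and takes
#' the requested linear-interpolation percentile.
#'
#' @param scanFn function mapping a [VariantTable-class] to a numeric
#'   vector of window statistic values.
#' @param sims list of [VariantTable-class] replicates.
#' @param q percentile in [0, 100] (99 for F_ST/XP-CLR upper tails, 0.1
#'   for the Hp lower tail).
#' @param statistic statistic label recorded in the result.
#' @param metadata optional list recorded in the result.
#' @return A [CalibrationResult-class].
#' @export
calibrateThreshold <- function(scanFn, sims, q, statistic = "stat",
                               metadata = list()) {
    vals <- lapply(sims, function(s) {
        v <- scanFn(s)
        v[is.finite(v)]
    })
    pooled <- unlist(vals, use.names = FALSE)
    if (!length(pooled)) stop("no finite window values to calibrate on")
    methods::new("CalibrationResult", statistic = statistic, q = q,
                 threshold = percentileThreshold(pooled, q),
                 nReplicates = length(sims), values = pooled,
                 perReplicate = lengths(vals), metadata = metadata)
}
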