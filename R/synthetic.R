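#' Specify a planted selective sweep
#'
#' Truth label for the synthetic-cohort generator: within the interval the
#' target population's diversity is collapsed onto one designated haplotype.
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param mode "fixed-haplotype" (all target chromosomes overwritten) or
#'   "frequency-raise" (a fraction `1 - residual` of chromosomes
#'   overwritten).
#' @param population target population ("dog").
#' @param residual residual diversity fraction in [0,1]: in fixed-haplotype
#'   mode, the fraction of sites left untouched; in frequency-raise mode,
#'   the fraction of chromosomes left untouched.
#' @param ancientCarrier should simulated ancient samples carry the swept
#'   haplotype?
#' @return length-1 GRanges with sweep metadata.
#' @export
sweepSpec <- function(chrom, start, end, mode = "fixed-haplotype",
                      population = "dog", residual = 0,
                      ancientCarrier = TRUE) {
    stopifnot(end > start, residual >= 0, residual <= 1,
              mode %in% c("fixed-haplotype", "frequency-raise"))
    gr <- GRanges(chrom, IRanges(start + 1, end))
    mcols(gr) <- DataFrame(mode = mode, population = population,
                           residual = residual,
                           ancientCarrier = ancientCarrier)
    gr
}

#' Specify a planted copy-number difference
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param dogCN,wolfCN named numeric vectors giving the true copy-number
#'   distribution per population: names are integer copy numbers (>= 0),
#'   values are probabilities summing to 1. Scalars are shorthand for a
#'   point mass, e.g. `dogCN = 4`.
#' @return length-1 GRanges with CNV metadata.
#' @export
cnvSpec <- function(chrom, start, end, dogCN = 4, wolfCN = 2) {
    asDist <- function(x) {
        if (is.null(names(x))) { names(x) <- as.character(x); x[] <- 1 }
        cn <- as.numeric(names(x))
        if (any(cn < 0) || any(cn != round(cn)))
            stop("copy numbers must be non-negative integers")
        if (abs(sum(x) - 1) > 1e-8) stop("copy-number probabilities must sum to 1")
        x
    }
    gr <- GRanges(chrom, IRanges(start + 1, end))
    mcols(gr) <- DataFrame(dogCN = I(list(asDist(dogCN))),
                           wolfCN = I(list(asDist(wolfCN))))
    gr
}

# site-wise majority haplotype over a 0/1 haplotype block; ties resolve to
# the reference (ancestral) allele, matching the major-allele convention of
# alleleFrequencies()
majorityHaplotype <- function(hapBlock) {
    as.integer(rowMeans(hapBlock) > 0.5)
}

#' Generate a synthetic dog/wolf cohort with planted sweeps
#'
#' Simulates neutral biallelic genotypes for `nDogs` village dogs and
#' `nWolves` wolves (plus `nAncient` reserved ancient dogs) under a
#' demographic model, using a structured coalescent over independent
#' non-recombining blocks, then imposes the requested sweeps by haplotype
#' overwriting so truth labels are exact. Sites monomorphic among the
#' modern samples are dropped.
#'
#' @param model A [DemographicModel-class]. Must contain a "dog" lineage
#'   (and a "wolf" lineage unless it has a single population, in which case
#'   all samples are drawn from it).
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param sweeps GRanges from [sweepSpec()] (concatenate with `c()`), or
#'   NULL.
#' @param nDogs,nWolves,nAncient sample counts; ancient samples are drawn
#'   from the dog lineage at time 0 and kept aside as neutral haplotypes
#'   until [generateAncientSamples()] applies the carrier policy.
#' @param seed integer seed (required; same seed, same cohort).
#' @param blockSize length of the independent coalescent blocks (bp).
#' @return A [SyntheticCohort-class].
#' @export
generateCohort <- function(model, chromLengths, sweeps = NULL, nDogs = 43,
                           nWolves = 10, nAncient = 2, seed,
                           blockSize = 20000) {
    stopifnot(nDogs >= 1, nWolves >= 0, all(chromLengths > 0))
    if (missing(seed)) stop("a seed is required for reproducibility")
    if (is.null(names(chromLengths)))
        names(chromLengths) <- paste0("chr", seq_along(chromLengths))
    if (is.null(sweeps)) sweeps <- GRanges()
    if (length(sweeps)) {
        if (any(IRanges::countOverlaps(sweeps, sweeps) > 1))
            stop("overlapping sweep intervals")
        bad <- !(as.character(seqnames(sweeps)) %in% names(chromLengths)) |
            end(sweeps) > chromLengths[as.character(seqnames(sweeps))]
        if (any(bad)) stop("sweep interval outside any chromosome")
    }

    pops <- model@populations$name
    singlePop <- length(pops) == 1L
    if (!singlePop && !all(c("dog", "wolf") %in% pops))
        stop("model must contain 'dog' and 'wolf' lineages (or a single lineage)")
    nPerPop <- integer(length(pops))
    names(nPerPop) <- pops
    if (singlePop) {
        nPerPop[1] <- 2L * (nDogs + nWolves + nAncient)
    } else {
        nPerPop["dog"] <- 2L * (nDogs + nAncient)
        nPerPop["wolf"] <- 2L * nWolves
    }
    # leaf column layout follows population order
    offs <- cumsum(c(0L, nPerPop))[seq_along(pops)]
    names(offs) <- pops
    if (singlePop) {
        dogCols <- seq_len(2L * nDogs)
        wolfCols <- 2L * nDogs + seq_len(2L * nWolves)
        ancCols <- 2L * (nDogs + nWolves) + seq_len(2L * nAncient)
    } else {
        dogCols <- offs["dog"] + seq_len(2L * nDogs)
        ancCols <- offs["dog"] + 2L * nDogs + seq_len(2L * nAncient)
        wolfCols <- offs["wolf"] + seq_len(2L * nWolves)
    }

    dc <- demogToCpp(model)
    set.seed(seed)
    allPos <- list(); allChrom <- list(); allHap <- list()
    for (ch in names(chromLengths)) {
        sim <- .simBlocksCpp(unname(nPerPop), dc$popSize0, dc$evTime,
                             dc$evType, dc$evPop, dc$evDest, dc$evValue,
                             chromLengths[[ch]], blockSize,
                             model@mutationRate)
        allPos[[ch]] <- sim$pos
        allChrom[[ch]] <- rep(ch, length(sim$pos))
        allHap[[ch]] <- sim$haplotypes
    }
    pos <- unlist(allPos, use.names = FALSE)
    chrom <- unlist(allChrom, use.names = FALSE)
    hap <- do.call(rbind, allHap)

    sites <- GRanges(chrom, IRanges(pos, width = 1),
                     seqlengths = chromLengths)
    modernCols <- c(dogCols, wolfCols)

    # impose sweeps on modern dog chromosomes
    sweepInfo <- vector("list", length(sweeps))
    if (length(sweeps)) {
        for (i in seq_along(sweeps)) {
            sw <- sweeps[i]
            idx <- which(IRanges::overlapsAny(sites, sw))
            if (!length(idx)) { sweepInfo[[i]] <- NULL; next }
            block <- hap[idx, dogCols, drop = FALSE]
            swept <- majorityHaplotype(block)
            # non-carrier ancients need a genuinely different haplotype at
            # the sites that stay variable after the sweep; the alternative
            # carries the non-swept allele at every interval site where the
            # pre-sweep cohort holds one (the maximally divergent haplotype
            # consistent with pre-sweep diversity), so the delta-Hp filter
            # sees the divergence in every window the sweep touches
            pre <- hap[idx, modernCols, drop = FALSE]
            poly <- rowSums(pre) > 0 & rowSums(pre) < ncol(pre)
            alt <- if (any(poly)) ifelse(poly, 1L - swept, swept) else NULL
            resid <- mcols(sw)$residual
            if (mcols(sw)$mode == "fixed-haplotype") {
                keep <- sample(length(idx), size = floor(resid * length(idx)))
                ovr <- setdiff(seq_along(idx), keep)
                hap[idx[ovr], dogCols] <- matrix(swept[ovr], length(ovr),
                                                 length(dogCols))
            } else { # frequency-raise: overwrite a fraction of chromosomes
                nOvr <- round((1 - resid) * length(dogCols))
                cols <- sample(dogCols, nOvr)
                hap[idx, cols] <- matrix(swept, length(idx), nOvr)
            }
            sweepInfo[[i]] <- list(idx = idx, swept = swept, alternative = alt)
        }
    }

    # drop sites monomorphic among modern samples
    ac <- rowSums(hap[, modernCols, drop = FALSE])
    keep <- ac > 0 & ac < length(modernCols)
    hap <- hap[keep, , drop = FALSE]
    sites <- sites[keep]
    newIdx <- cumsum(keep)
    for (i in seq_along(sweepInfo)) {
        si <- sweepInfo[[i]]
        if (is.null(si)) next
        kept <- keep[si$idx]
        sweepInfo[[i]] <- list(idx = newIdx[si$idx][kept],
                               swept = si$swept[kept],
                               alternative = si$alternative[kept])
    }

    # diploid dosages
    pair <- function(cols) {
        m <- hap[, cols, drop = FALSE]
        m[, seq(1, length(cols), 2), drop = FALSE] +
            m[, seq(2, length(cols), 2), drop = FALSE]
    }
    gt <- cbind(pair(dogCols), pair(wolfCols))
    panel <- data.frame(
        sample = c(sprintf("dog%02d", seq_len(nDogs)),
                   sprintf("wolf%02d", seq_len(nWolves))),
        population = c(rep("dog", nDogs), rep("wolf", nWolves)),
        sex = rep(c("female", "male"), length.out = nDogs + nWolves),
        stringsAsFactors = FALSE)
    vt <- VariantTable(gt, sites, panel)
    methods::new("SyntheticCohort", variants = vt, sweeps = sweeps,
                 cnvs = GRanges(),
                 ancientHaplotypes = hap[, ancCols, drop = FALSE],
                 sweepHaplotypes = sweepInfo)
}

#' Draw ancient dog genotypes under the sweep carrier policy
#'
#' Converts the cohort's reserved neutral ancient haplotypes into diploid
#' genotypes at the cohort's variant sites. At each planted sweep, ancient
#' samples are made homozygous for the swept haplotype when
#' `ancientCarrier` is TRUE, or homozygous for a stored pre-sweep
#' alternative haplotype when FALSE (an error if the sweep left no
#' alternative diversity to draw from).
#'
#' @param cohort A [SyntheticCohort-class].
#' @param nAncient number of ancient samples to emit (<= reserved).
#' @param carrierPolicy optional logical vector overriding the per-sweep
#'   `ancientCarrier` flags.
#' @param seed integer seed.
#' @return the cohort with `ancientGenotypes` filled in.
#' @export
generateAncientSamples <- function(cohort, nAncient = 2,
                                   carrierPolicy = NULL, seed = 1) {
    hapA <- cohort@ancientHaplotypes
    if (nAncient < 1) stop("nAncient must be >= 1")
    if (ncol(hapA) < 2 * nAncient)
        stop("cohort reserved only ", ncol(hapA) / 2, " ancient samples")
    hapA <- hapA[, seq_len(2 * nAncient), drop = FALSE]
    sweeps <- cohort@sweeps
    carrier <- if (is.null(carrierPolicy)) {
        if (length(sweeps)) mcols(sweeps)$ancientCarrier else logical()
    } else carrierPolicy
    if (length(sweeps) && length(carrier) != length(sweeps))
        stop("carrier policy must be defined for every sweep")
    set.seed(seed)
    for (i in seq_along(sweeps)) {
        si <- cohort@sweepHaplotypes[[i]]
        if (is.null(si) || !length(si$idx)) next
        if (carrier[i]) {
            hapA[si$idx, ] <- matrix(si$swept, length(si$idx), ncol(hapA))
        } else {
            if (is.null(si$alternative))
                stop("sweep ", i, ": no pre-sweep alternative haplotype stored ",
                     "(zero residual diversity) for a non-carrier policy")
            hapA[si$idx, ] <- matrix(si$alternative, length(si$idx),
                                     ncol(hapA))
        }
    }
    gtA <- hapA[, seq(1, 2 * nAncient, 2), drop = FALSE] +
        hapA[, seq(2, 2 * nAncient, 2), drop = FALSE]
    colnames(gtA) <- sprintf("ancient%02d", seq_len(nAncient))
    cohort@ancientGenotypes <- gtA
    cohort
}

#' Default GC bias curve
#'
#' Smooth unimodal multiplicative bias peaking at GC = 0.45 with factor
#' range [0.6, 1.1].
#' @param gc GC fraction in [0,1].
#' @return multiplicative depth factor.
#' @export
defaultGcBias <- function(gc) 0.6 + 0.5 * exp(-(gc - 0.45)^2 / (2 * 0.12^2))

#' Generate windowed read-depth tracks with planted copy-number differences
#'
#' Per-sample windowed depth is
#' `meanDepth * (CN / 2) * gcBias(GC) * (1 + N(0, noiseSd))`, truncated at
#' zero. True copy number is 2 outside the planted intervals; inside, each
#' sample draws its copy number from its population's specified
#' distribution (constant across the interval's windows). GC fractions are
#' drawn once per window from a Beta distribution centred at 0.42.
#'
#' @param cohort A [SyntheticCohort-class] (supplies panel and chromosome
#'   lengths).
#' @param cnvs GRanges from [cnvSpec()] or NULL.
#' @param windowSize window size in bp (default 3000).
#' @param meanDepth expected depth of a diploid window at bias 1.
#' @param gcBiasCurve function GC fraction -> positive factor.
#' @param noiseSd relative Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return the cohort with a [DepthProfiles-class] in its `depth` slot and
#'   the CNV truth recorded.
#' @export
generateDepthProfiles <- function(cohort, cnvs = NULL, windowSize = 3000,
                                  meanDepth = 30,
                                  gcBiasCurve = defaultGcBias,
                                  noiseSd = 0.05, seed = 1) {
    if (windowSize <= 0) stop("windowSize must be > 0")
    stopifnot(meanDepth > 0)
    if (is.null(cnvs)) cnvs <- GRanges()
    chromLengths <- GenomeInfoDb::seqlengths(rowRanges(cohort@variants))
    win <- makeWindows(chromLengths, windowSize, windowSize)
    panel <- samplePanel(cohort@variants)
    nS <- nrow(panel)
    set.seed(seed)
    gc <- stats::rbeta(length(win), 20.4, 28.2)
    fac <- gcBiasCurve(gc)
    if (any(fac <= 0)) stop("gcBiasCurve must return positive factors")
    cn <- matrix(2, length(win), nS,
                 dimnames = list(NULL, panel$sample))
    if (length(cnvs)) {
        within <- findOverlaps(win, cnvs, type = "within")
        for (i in seq_along(cnvs)) {
            rows <- S4Vectors::queryHits(within)[S4Vectors::subjectHits(within) == i]
            if (!length(rows)) next
            for (s in seq_len(nS)) {
                dist <- if (panel$population[s] == "wolf")
                    mcols(cnvs)$wolfCN[[i]] else mcols(cnvs)$dogCN[[i]]
                cnVal <- as.numeric(names(dist))[
                    sample.int(length(dist), 1, prob = dist)]
                cn[rows, s] <- cnVal
            }
        }
    }
    noise <- matrix(stats::rnorm(length(win) * nS, 0, noiseSd),
                    length(win), nS)
    depth <- pmax(meanDepth * (cn / 2) * fac * (1 + noise), 0)
    colnames(depth) <- panel$sample
    rd <- win
    mcols(rd)$gc <- gc
    mcols(rd)$control <- !IRanges::overlapsAny(win, cnvs)
    mcols(rd)$regionClass <- regionClassOf(win)
    cd <- DataFrame(population = panel$population, sex = panel$sex,
                    row.names = panel$sample)
    dp <- methods::new("DepthProfiles",
        SummarizedExperiment(assays = list(depth = depth, trueCN = cn),
                             rowRanges = rd, colData = cd))
    cohort@depth <- dp
    cohort@cnvs <- cnvs
    cohort
}

#' Generate a toy gene set and GO-style ontology
#'
#' Non-overlapping gene intervals, a rooted term DAG in which every
#' non-root term has at least one parent, and gene-to-term annotations.
#' Ancestor propagation is performed by [buildOntology()] downstream.
#'
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param nGenes,nTerms counts (>= 1).
#' @param ontologyDepth maximum depth of the term DAG below the root.
#' @param seed integer seed.
#' @return list with `genes` (GRanges with `gene_id`), `annotation`
#'   (data.frame gene/term, direct annotations only) and `ontology`
#'   (data.frame child/parent).
#' @export
generateToyAnnotation <- function(chromLengths, nGenes = 200,
                                  ontologyDepth = 3, nTerms = 50, seed = 1) {
    stopifnot(nGenes >= 1, nTerms >= 1)
    if (is.null(names(chromLengths)))
        names(chromLengths) <- paste0("chr", seq_along(chromLengths))
    set.seed(seed)
    # distribute genes over chromosomes proportionally to length
    alloc <- round(nGenes * chromLengths / sum(chromLengths))
    while (sum(alloc) < nGenes) alloc[which.max(chromLengths)] <- alloc[which.max(chromLengths)] + 1
    while (sum(alloc) > nGenes) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1
    grl <- list()
    gid <- 0L
    for (ch in names(chromLengths)) {
        k <- alloc[[ch]]
        if (k == 0) next
        lens <- round(stats::runif(k, 5000, 50000))
        free <- chromLengths[[ch]] - sum(lens)
        if (free < 0) stop("genes cannot fit on ", ch, " without overlap")
        cuts <- sort(stats::runif(k, 0, 1))
        gaps <- diff(c(0, cuts)) * free
        starts <- cumsum(gaps) + cumsum(c(0, lens[-k]))
        grl[[ch]] <- GRanges(ch, IRanges(floor(starts) + 1,
                                         width = lens),
                             gene_id = sprintf("gene%04d", gid + seq_len(k)))
        gid <- gid + k
    }
    genes <- unlist(methods::as(grl, "GRangesList"), use.names = FALSE)
    GenomeInfoDb::seqlengths(genes) <- chromLengths[GenomeInfoDb::seqlevels(genes)]

    terms <- sprintf("T%04d", seq_len(nTerms))
    level <- c(0L, if (nTerms > 1)
        sample(seq_len(max(1L, ontologyDepth)), nTerms - 1L, replace = TRUE))
    level <- sort(level)
    edges <- NULL
    for (i in seq_len(nTerms)[-1]) {
        cand <- which(level < level[i])
        nPar <- min(length(cand), sample(1:2, 1))
        par <- sample(cand, nPar)
        edges <- rbind(edges, data.frame(child = terms[i],
                                         parent = terms[par],
                                         stringsAsFactors = FALSE))
    }
    if (is.null(edges))
        edges <- data.frame(child = character(), parent = character(),
                            stringsAsFactors = FALSE)
    ann <- do.call(rbind, lapply(genes$gene_id, function(g) {
        k <- sample(1:3, 1)
        data.frame(gene = g, term = sample(terms, min(k, nTerms)),
                   stringsAsFactors = FALSE)
    }))
    list(genes = genes, annotation = unique(ann), ontology = edges)
}

#' Align ancient genotypes with a (filtered) VariantTable
#'
#' Subsets the cohort's ancient genotype matrix to the rows of `vt`, which
#' is typically the cohort's variant table after further site filtering.
#'
#' @param cohort A [SyntheticCohort-class] with ancient genotypes drawn.
#' @param vt A [VariantTable-class] whose sites are a subset of the
#'   cohort's.
#' @return dosage matrix with `nrow(vt)` rows.
#' @export
alignAncientGenotypes <- function(cohort, vt) {
    if (is.null(cohort@ancientGenotypes))
        stop("cohort has no ancient genotypes; run generateAncientSamples")
    key <- function(g) paste0(seqnames(g), ":", start(g))
    i <- match(key(rowRanges(vt)), key(rowRanges(cohort@variants)))
    if (anyNA(i)) stop("vt contains sites absent from the cohort")
    cohort@ancientGenotypes[i, , drop = FALSE]
}
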