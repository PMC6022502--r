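test_that("cohort generation is deterministic given the seed", {
    m <- testModel()
    a <- generateCohort(m, c(chr1 = 5e5), nDogs = 5, nWolves = 5,
                        nAncient = 1, seed = 3)
    b <- generateCohort(m, c(chr1 = 5e5), nDogs = 5, nWolves = 5,
                        nAncient = 1, seed = 3)
    expect_identical(genotypes(cohortVariants(a)),
                     genotypes(cohortVariants(b)))
    expect_identical(start(rowRanges(cohortVariants(a))),
                     start(rowRanges(cohortVariants(b))))
    c2 <- generateCohort(m, c(chr1 = 5e5), nDogs = 5, nWolves = 5,
                         nAncient = 1, seed = 4)
    expect_false(identical(start(rowRanges(cohortVariants(a))),
                           start(rowRanges(cohortVariants(c2)))))
})

test_that("a panmictic model yields near-zero mean F_ST", {
    m <- DemographicModel(populations = data.frame(name = "dog",
                                                   size = 15000))
    co <- generateCohort(m, c(chr1 = 3e6), nDogs = 43, nWolves = 43,
                        nAncient = 0, seed = 5)
    f <- siteFst(alleleFrequencies(cohortVariants(co)))
    # the individuals-based sample-size convention carries a small O(1/n)
    # negative offset (~ -0.012 at n = 43), so "near zero" means within it
    expect_lt(abs(mean(f$fst)), 0.025)
})

test_that("sweep validation rejects bad intervals", {
    m <- testModel()
    s1 <- sweepSpec("chr1", 1e5, 3e5)
    s2 <- sweepSpec("chr1", 2e5, 4e5)
    expect_error(generateCohort(m, c(chr1 = 5e5), sweeps = c(s1, s2),
                                seed = 1), "overlapping")
    s3 <- sweepSpec("chr2", 1e5, 3e5)
    expect_error(generateCohort(m, c(chr1 = 5e5), sweeps = s3, seed = 1),
                 "outside")
    expect_error(generateCohort(m, c(chr1 = 5e5)), "seed")
})

test_that("a zero-residual sweep drives dog Hp to zero in contained windows", {
    sw <- sweepSpec("chr1", 5e5, 1e6, residual = 0)
    co <- generateCohort(testModel(), c(chr1 = 2e6), sweeps = sw,
                         nDogs = 20, nWolves = 10, nAncient = 2, seed = 6)
    fr <- alleleFrequencies(cohortVariants(co))
    w <- windowHp(fr, makeWindows(c(chr1 = 2e6), 25000, 25000))
    contained <- IRanges::overlapsAny(w, GRanges("chr1",
        IRanges(5e5 + 1, 1e6)), type = "within")
    hp <- mcols(w)$hp[contained]
    expect_true(all(hp[!is.na(hp)] == 0))
    # direct computation on the emitted genotypes agrees
    gt <- genotypes(cohortVariants(co))
    dog <- samplePanel(cohortVariants(co))$population == "dog"
    inSweep <- IRanges::overlapsAny(rowRanges(cohortVariants(co)),
        GRanges("chr1", IRanges(5e5 + 1, 1e6)))
    dAlt <- rowSums(gt[inSweep, dog, drop = FALSE])
    expect_true(all(dAlt %in% c(0, 2 * sum(dog))))
})

test_that("windows inside swept intervals sit below the genome-wide Hp median", {
    ok <- 0L
    for (seed in 1:5) {
        sw <- sweepSpec("chr1", 8e5, 1.3e6, residual = 0.1)
        co <- generateCohort(testModel(), c(chr1 = 3e6), sweeps = sw,
                             nDogs = 20, nWolves = 10, nAncient = 0,
                             seed = 40 + seed)
        fr <- alleleFrequencies(mafFilter(cohortVariants(co)))
        w <- windowHp(fr, makeWindows(c(chr1 = 3e6), 25000, 25000))
        hp <- mcols(w)$hp
        med <- stats::median(hp, na.rm = TRUE)
        contained <- IRanges::overlapsAny(w, GRanges("chr1",
            IRanges(8e5 + 1, 1.3e6)), type = "within")
        if (all(hp[contained][!is.na(hp[contained])] < med)) ok <- ok + 1L
    }
    expect_gte(ok, 4L)
})

test_that("ancient carrier policy shapes delta-Hp as designed", {
    sw <- c(sweepSpec("chr1", 2e5, 6e5, residual = 0.05,
                      ancientCarrier = TRUE),
            sweepSpec("chr1", 1.2e6, 1.6e6, residual = 0.05,
                      ancientCarrier = FALSE))
    co <- generateCohort(testModel(), c(chr1 = 2e6), sweeps = sw,
                         nDogs = 20, nWolves = 10, nAncient = 2, seed = 8)
    co <- generateAncientSamples(co, seed = 9)
    vt <- cohortVariants(co)
    fr <- alleleFrequencies(vt)
    anc <- alignAncientGenotypes(co, vt)
    w <- deltaHp(fr, anc, makeWindows(c(chr1 = 2e6), 25000, 25000))
    carrier <- IRanges::overlapsAny(w, GRanges("chr1",
        IRanges(2e5 + 1, 6e5)), type = "within")
    nonCarrier <- IRanges::overlapsAny(w, GRanges("chr1",
        IRanges(1.2e6 + 1, 1.6e6)), type = "within")
    dC <- mcols(w)$deltaHp[carrier]
    dN <- mcols(w)$deltaHp[nonCarrier]
    expect_true(all(dC[!is.na(dC)] <= 1e-12))
    expect_true(all(dN[!is.na(dN)] > 0))
})

test_that("without sweeps, ancient samples look like modern dogs", {
    co <- cachedNeutralCohort()
    vt <- cohortVariants(co)
    anc <- ancientGenotypes(co)
    dog <- samplePanel(vt)$population == "dog"
    gt <- genotypes(vt)
    kMod <- rowSums(gt[, dog])
    kAnc <- rowSums(anc)
    # exact (Fisher/hypergeometric) two-proportion test per site:
    # 4 ancient vs 2 * nDogs modern chromosomes
    nA <- 4L
    nM <- 2L * sum(dog)
    K <- kMod + kAnc
    pObs <- stats::dhyper(kAnc, K, nM + nA - K, nA)
    pval <- vapply(seq_along(K), function(i) {
        probs <- stats::dhyper(0:nA, K[i], nM + nA - K[i], nA)
        sum(probs[probs <= pObs[i] + 1e-12])
    }, numeric(1))
    expect_gt(mean(pval > 0.01), 0.99)
})

test_that("depth generation follows the copy-number and bias model exactly", {
    co <- generateCohort(testModel(), c(chr1 = 3e5), nDogs = 4, nWolves = 4,
                         nAncient = 1, seed = 10)
    flat <- function(gc) rep(1, length(gc))

    noNoise <- generateDepthProfiles(co, cnvs = NULL, meanDepth = 30,
                                     gcBiasCurve = flat, noiseSd = 0,
                                     seed = 2)
    expect_true(all(assay(cohortDepth(noNoise), "depth") == 30))

    cnv <- cnvSpec("chr1", 60000, 90000, dogCN = 4, wolfCN = 2)
    dup <- generateDepthProfiles(co, cnvs = cnv, meanDepth = 30,
                                 gcBiasCurve = flat, noiseSd = 0, seed = 2)
    d <- assay(cohortDepth(dup), "depth")
    rows <- IRanges::overlapsAny(rowRanges(cohortDepth(dup)),
        GRanges("chr1", IRanges(60001, 90000)), type = "within")
    pops <- samplePanel(cohortVariants(co))$population
    expect_true(all(d[rows, pops == "dog"] == 60))
    expect_true(all(d[rows, pops == "wolf"] == 30))
    expect_true(all(d[!rows, ] == 30))
    expect_error(generateDepthProfiles(co, windowSize = 0), "windowSize")
})

test_that("per-sample SNR reflects the injected noise level", {
    co <- generateCohort(testModel(), c(chr1 = 3.2e7), nDogs = 2,
                         nWolves = 2, nAncient = 1, seed = 11,
                         blockSize = 1e6)
    flat <- function(gc) rep(1, length(gc))
    dp <- generateDepthProfiles(co, meanDepth = 50, gcBiasCurve = flat,
                                noiseSd = 0.1, seed = 3)
    snr <- sampleSnr(cohortDepth(dp))
    expect_true(all(abs(snr - 10) / 10 < 0.1))
})

test_that("toy annotation builds a rooted, propagated, reproducible fixture", {
    a1 <- generateToyAnnotation(c(chr1 = 5e6), nGenes = 50, nTerms = 12,
                                ontologyDepth = 3, seed = 2)
    a2 <- generateToyAnnotation(c(chr1 = 5e6), nGenes = 50, nTerms = 12,
                                ontologyDepth = 3, seed = 2)
    expect_identical(a1, a2)

    # genes do not overlap
    expect_true(all(IRanges::countOverlaps(a1$genes, a1$genes) == 1))

    # every non-root term has a parent; single root
    kids <- unique(a1$ontology$child)
    allTerms <- unique(c(a1$annotation$term, kids, a1$ontology$parent))
    expect_setequal(setdiff(allTerms, kids), "T0001")

    # propagation closure: root annotates every gene
    onto <- buildOntology(a1$annotation, a1$ontology)
    expect_setequal(onto$term2genes[["T0001"]], a1$genes$gene_id)

    # leaf annotation counts for every ancestor
    leaf <- a1$annotation$term[1]
    g <- a1$annotation$gene[1]
    for (t in onto$ancestors[[leaf]])
        expect_true(g %in% onto$term2genes[[t]])

    # single-term fixture: one root annotating all genes
    a3 <- generateToyAnnotation(c(chr1 = 5e6), nGenes = 10, nTerms = 1,
                                seed = 3)
    expect_equal(unique(a3$annotation$term), "T0001")
    expect_setequal(a3$annotation$gene, a3$genes$gene_id)
})

test_that("neutral threshold calibration is self-consistent across replicates", {
    sims <- lapply(simulateNeutral(testModel(), c(chr1 = 2e6), reps = 4,
                                   seed = 60, nDogs = 20, nWolves = 10),
                   mafFilter)
    cal <- calibrateThreshold(function(s) {
        f <- siteFst(alleleFrequencies(s))
        mcols(windowedFst(f, makeWindows(c(chr1 = 2e6), 2e5, 5e4)))$value
    }, sims, 99, statistic = "fst")
    expect_equal(calibratedThreshold(cal),
                 percentileThreshold(calibrationValues(cal), 99))
    # monotone in q
    expect_gte(percentileThreshold(calibrationValues(cal), 99),
               percentileThreshold(calibrationValues(cal), 95))
    expect_error(simulateNeutral(testModel(), c(chr1 = 1e5), reps = 2,
                                 seeds = c(7, 7)), "distinct")
})

test_that("SNP matching thins to the real counts and preserves the spectrum", {
    co <- cachedNeutralCohort()
    vt <- cohortVariants(co)
    thinned <- matchRealSnps(vt, c(chr1 = 2000), seed = 5)
    expect_equal(nrow(thinned), 2000)
    expect_error(matchRealSnps(vt, c(chr1 = 1e7), seed = 5), "required")
    # spectrum shape is preserved under uniform thinning
    pFull <- alleleFrequencies(mafFilter(vt))$pDog
    pThin <- alleleFrequencies(thinned)$pDog
    ks <- suppressWarnings(stats::ks.test(pThin, pFull))
    expect_gt(ks$p.value, 0.01)
})
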