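test_that("genetic distances interpolate and extrapolate linearly", {
    map <- data.frame(pos = c(0, 1e6), morgans = c(0, 0.01))
    expect_equal(geneticDistances(5e5, map), 0.005)
    expect_equal(geneticDistances(1e6, map), 0.01)
    expect_equal(geneticDistances(1.5e6, map), 0.015) # terminal-rate extrapolation
    expect_equal(geneticDistances(2.5e6, rate = 1e-8), 0.025)
    bad <- data.frame(pos = c(1e6, 0), morgans = c(0.01, 0))
    expect_error(geneticDistances(1, bad), "unsorted")
})

test_that("identical dog and wolf frequencies give near-zero scores", {
    set.seed(4)
    fr <- randomFreqs(400, seed = 4)
    fr$pDog <- fr$pWolf
    g <- xpclrScoreGrid(fr, c(chr1 = 1e6),
                        xpclrConfig(gridSpacing = 50000))
    sc <- mcols(g)$score
    expect_true(all(sc[!is.na(sc)] >= 0))
    expect_lt(max(sc, na.rm = TRUE), 0.5)
})

test_that("restricting the selection grid to s = 0 forces zero scores", {
    fr <- randomFreqs(300, seed = 9)
    g <- xpclrScoreGrid(fr, c(chr1 = 1e6),
                        xpclrConfig(gridSpacing = 50000, sGrid = 0))
    sc <- mcols(g)$score
    expect_true(all(sc[!is.na(sc)] == 0))
})

test_that("stronger dog-wolf differentiation never lowers the grid score", {
    # fixed positions; dogs progressively diverge from a wolf freq of 0.5
    set.seed(10)
    pos <- sort(sample(5e4, 40))
    base <- data.frame(chrom = "chr1", pos = pos, regionClass = "autosome",
                       pWolf = 0.5, nDog = 43, nWolf = 10,
                       nMAJ = 60, nMIN = 26, majorIsRef = TRUE)
    cfg <- xpclrConfig(gridSpacing = 50000, omega = 0.2)
    prev <- -Inf
    for (p1 in c(0.5, 0.7, 0.9, 1.0)) {
        fr <- base
        fr$pDog <- p1
        sc <- mcols(xpclrScoreGrid(fr, c(chr1 = 5e4), cfg))$score[1]
        expect_gte(sc, prev - 1e-9)
        prev <- sc
    }
    expect_gt(prev, 0)
})

test_that("grid points with no usable SNP are flagged failed", {
    fr <- randomFreqs(20, seed = 2, span = 5e4)
    g <- xpclrScoreGrid(fr, c(chr1 = 1e6), xpclrConfig(gridSpacing = 2e5))
    expect_true(any(is.na(mcols(g)$score)))
    expect_true(all(mcols(g)$nSnps[is.na(mcols(g)$score)] == 0))
})

test_that("window averaging enforces the minimum-grid rule", {
    g <- GRanges("chr1", IRanges(seq(1000, 25000, 2000), width = 1))
    mcols(g)$score <- rep(10, length(g))
    mcols(g)$nSnps <- 5L

    # only 4 passing grids in the window -> removed
    g4 <- g[1:4]
    w4 <- averageGridWindows(g4, c(chr1 = 25000), win = 25000, step = 25000)
    expect_true(is.na(mcols(w4)$value))
    expect_false(mcols(w4)$pass_support)

    # 5 equal scores -> the common value
    g5 <- g[1:5]
    w5 <- averageGridWindows(g5, c(chr1 = 25000), win = 25000, step = 25000)
    expect_equal(mcols(w5)$value, 10)

    # [10, 20, 30, 40, 50] -> 30, and permutation invariance
    mcols(g5)$score <- c(10, 20, 30, 40, 50)
    expect_equal(mcols(averageGridWindows(g5, c(chr1 = 25000),
        win = 25000, step = 25000))$value, 30)
    mcols(g5)$score <- c(50, 30, 10, 40, 20)
    expect_equal(mcols(averageGridWindows(g5, c(chr1 = 25000),
        win = 25000, step = 25000))$value, 30)
})

test_that("candidate calling composes score, Hp and delta-Hp filters", {
    w <- GRanges("chr1", IRanges(c(1, 40001, 130001), width = 25000))
    mcols(w)$value <- c(30, 30, 30)
    mcols(w)$hp <- c(0.01, 0.01, 0.20)
    mcols(w)$deltaHp <- c(-0.002, -0.002, -0.002)
    # 45-kb gap between passing windows 1 and 2 -> one region
    cand <- xpclrCandidates(w, threshold = 20, hpThreshold = 0.06,
                            dhpThreshold = 0)
    expect_length(cand, 1)
    expect_equal(c(start(cand), end(cand)), c(1, 65000))

    # high score but high Hp -> excluded (window 3 above)
    expect_false(IRanges::overlapsAny(GRanges("chr1",
        IRanges(130001, 155000)), cand))

    # ancient on a different haplotype -> excluded
    mcols(w)$deltaHp <- c(0.05, -0.002, -0.002)
    cand2 <- xpclrCandidates(w, 20, 0.06, 0)
    expect_equal(start(cand2), 40001)
    expect_error(xpclrCandidates(w, NA, 0.06, 0), "threshold")
})

test_that("grid scores inside a planted sweep exceed the neutral tail", {
    co <- cachedNeutralCohort()
    frN <- alleleFrequencies(mafFilter(cohortVariants(co)))
    gN <- xpclrScoreGrid(frN, c(chr1 = 4e6))
    neutral99 <- percentileThreshold(
        mcols(gN)$score[!is.na(mcols(gN)$score)], 99)

    sw <- sweepSpec("chr1", 1.5e6, 2.0e6, residual = 0.02)
    coS <- generateCohort(testModel(), c(chr1 = 4e6), sweeps = sw,
                          nDogs = 43, nWolves = 10, nAncient = 2, seed = 31)
    frS <- alleleFrequencies(mafFilter(cohortVariants(coS)))
    gS <- xpclrScoreGrid(frS, c(chr1 = 4e6))
    inside <- IRanges::overlapsAny(gS, GRanges("chr1",
        IRanges(1.6e6, 1.9e6)))
    sc <- mcols(gS)$score[inside]
    # sparse post-sweep SNP support makes individual grid points noisy;
    # the bulk of the swept grid must clear the sweep-free 99th percentile
    expect_gt(stats::median(sc, na.rm = TRUE), neutral99)
    expect_gt(mean(sc[!is.na(sc)] > neutral99), 0.5)
})
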