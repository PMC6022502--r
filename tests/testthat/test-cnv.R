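# DepthProfiles built directly from a depth matrix on tiled 3-kb windows
makeDP <- function(depth, gc = NULL, control = NULL, chrom = "chr1") {
    n <- nrow(depth)
    win <- GRanges(chrom, IRanges(3000 * (seq_len(n) - 1) + 1, width = 3000))
    if (is.null(gc)) gc <- rep(0.4, n)
    if (is.null(control)) control <- rep(TRUE, n)
    mcols(win)$gc <- gc
    mcols(win)$control <- control
    mcols(win)$regionClass <- regionClassOf(win)
    pn <- makePanel(ncol(depth) / 2, ncol(depth) / 2)
    colnames(depth) <- pn$sample
    cd <- DataFrame(population = pn$population, sex = pn$sex,
                    row.names = pn$sample)
    methods::new("DepthProfiles", SummarizedExperiment(
        assays = list(depth = depth), rowRanges = win, colData = cd))
}

test_that("GC correction rescales by bin and flags empty bins", {
    # uniform GC: correction is the identity
    d <- matrix(rep(c(30, 40), each = 50), 100, 4)
    dp <- makeDP(d)
    out <- gcCorrectDepth(dp, minBin = 10)
    expect_equal(assay(out, "corrected"), assay(out, "depth"))

    # a known bias curve is inverted up to noise
    set.seed(1)
    n <- 6000
    gc <- stats::rbeta(n, 20, 28)
    bias <- defaultGcBias(gc)
    noise <- matrix(stats::rnorm(n * 2, 0, 0.05), n, 2)
    d2 <- 30 * bias * (1 + noise)
    dp2 <- makeDP(d2, gc = gc)
    out2 <- gcCorrectDepth(dp2, minBin = 20)
    cv <- apply(assay(out2, "corrected"), 2,
                function(x) stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE))
    expect_true(all(cv < 0.05 * 1.1))

    # window in a bin with too few control windows is uncorrectable
    gc3 <- c(rep(0.4, 99), 0.99)
    dp3 <- makeDP(matrix(30, 100, 2), gc = gc3)
    out3 <- gcCorrectDepth(dp3, minBin = 10)
    expect_true(all(is.na(assay(out3, "corrected")[100, ])))
    expect_false(anyNA(assay(out3, "corrected")[1:99, ]))
})

test_that("copy number anchors control windows at two", {
    d <- matrix(30, 50, 4)
    d[10, ] <- 60   # doubled depth
    d[11, ] <- 0
    ctrl <- rep(TRUE, 50); ctrl[10:11] <- FALSE
    cn <- estimateCopyNumber(gcCorrectDepth(makeDP(d, control = ctrl),
                                            minBin = 5))
    m <- assay(cn, "CN")
    expect_true(all(m[-c(10, 11), ] == 2))
    expect_true(all(m[10, ] == 4))
    expect_true(all(m[11, ] == 0))
})

test_that("noise-free planted copy numbers are recovered exactly", {
    co <- generateCohort(testModel(), c(chr1 = 3e5), nDogs = 3, nWolves = 3,
                         nAncient = 1, seed = 13)
    flat <- function(gc) rep(1, length(gc))
    cnv <- cnvSpec("chr1", 90000, 150000, dogCN = c("4" = 0.5, "6" = 0.5),
                   wolfCN = 2)
    co <- generateDepthProfiles(co, cnvs = cnv, meanDepth = 25,
                                gcBiasCurve = flat, noiseSd = 0, seed = 4)
    cn <- estimateCopyNumber(cohortDepth(co))
    expect_equal(assay(cn, "CN"), assay(cohortDepth(co), "trueCN"),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("SNR matches its definition and is scale invariant", {
    set.seed(2)
    d <- matrix(stats::rnorm(20000, 100, 10), 10000, 2)
    dp <- makeDP(d)
    snr <- sampleSnr(dp)
    expect_true(all(abs(snr - 10) / 10 < 0.1))
    expect_equal(sampleSnr(makeDP(2 * d)), snr, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_error(sampleSnr(makeDP(matrix(5, 100, 2))), "constant")
})

test_that("V_ST matches hand arithmetic and the variance decomposition", {
    mkCN <- function(dogCN, wolfCN) {
        m <- matrix(c(dogCN, wolfCN), nrow = 1)
        n <- length(dogCN)
        win <- GRanges("chr1", IRanges(1, 3000))
        mcols(win)$regionClass <- "autosome"
        pn <- makePanel(n, length(wolfCN))
        colnames(m) <- pn$sample
        methods::new("CopyNumberTable", SummarizedExperiment(
            assays = list(CN = m), rowRanges = win,
            colData = DataFrame(population = pn$population, sex = pn$sex,
                                row.names = pn$sample)))
    }
    expect_equal(mcols(vstScan(mkCN(c(2, 2, 2), c(4, 4, 4))))$vst, 1)
    expect_equal(mcols(vstScan(mkCN(c(2, 2, 4, 4), c(2, 2, 4, 4))))$vst, 0)
    r <- vstScan(mkCN(c(2, 2, 2, 2), c(2, 2, 4, 4)))
    expect_equal(mcols(r)$vt, 0.75, tolerance = 1e-12)
    expect_equal(mcols(r)$vs, 0.5, tolerance = 1e-12)
    expect_equal(mcols(r)$vst, 1 / 3, tolerance = 1e-12)
    expect_equal(mcols(r)$cnRange, 2)

    # V_T = 0 emits no value; tiny populations are an error
    expect_true(is.na(mcols(vstScan(mkCN(c(2, 2), c(2, 2))))$vst))
    expect_error(vstScan(mkCN(c(2, 2), 4)), ">= 2")

    # brute-force variance-decomposition oracle on random inputs
    set.seed(3)
    for (i in 1:50) {
        nd <- sample(2:8, 1); nw <- sample(2:8, 1)
        dc <- sample(0:6, nd, replace = TRUE)
        wc <- sample(0:6, nw, replace = TRUE)
        v <- mcols(vstScan(mkCN(dc, wc)))$vst
        all <- c(dc, wc)
        vT <- mean((all - mean(all))^2)
        vS <- (mean((dc - mean(dc))^2) * nd +
               mean((wc - mean(wc))^2) * nw) / (nd + nw)
        expected <- if (vT > 0) (vT - vS) / vT else NA_real_
        expect_equal(v, expected, tolerance = 1e-12)
        if (!is.na(v)) expect_lte(v, 1)
    }
})

test_that("male X-nonPAR copy numbers are doubled before V_ST", {
    win <- GRanges("chrX", IRanges(c(1, 3001), width = 3000))
    mcols(win)$regionClass <- "X-nonPAR"
    pn <- makePanel(2, 2, sexes = c("male", "female", "male", "female"))
    m <- matrix(c(1, 2, 1, 2,   # haploid males at CN 1 == diploid 2
                  2, 2, 2, 2), 2, 4, byrow = TRUE)
    colnames(m) <- pn$sample
    cn <- methods::new("CopyNumberTable", SummarizedExperiment(
        assays = list(CN = m), rowRanges = win,
        colData = DataFrame(population = pn$population, sex = pn$sex,
                            row.names = pn$sample)))
    r <- vstScan(cn)
    expect_true(is.na(mcols(r)$vst[1]))   # all equal after doubling
    expect_equal(mcols(r)$cnRange[1], 0)
})

test_that("V_ST outlier calling needs range, Z and multi-window support", {
    n <- 400
    win <- GRanges("chr1", IRanges(3000 * (seq_len(n) - 1) + 1,
                                   width = 3000))
    set.seed(8)
    rec <- win
    mcols(rec)$vst <- stats::rnorm(n, 0, 0.02)
    mcols(rec)$cnRange <- rep(2, n)
    mcols(rec)$regionClass <- rep("autosome", n)
    mcols(rec)$vt <- 1; mcols(rec)$vs <- 0.5

    base <- rec
    # two adjacent strong windows -> one region kept
    mcols(base)$vst[201:202] <- 0.9
    out <- callVstOutliers(base)
    expect_length(out, 1)
    expect_equal(mcols(out)$nWindows, 2L)

    # a single isolated strong window is discarded
    one <- rec
    mcols(one)$vst[300] <- 0.9
    expect_length(callVstOutliers(one), 0)

    # high Z but insufficient copy-number range -> dropped
    low <- base
    mcols(low)$cnRange[201:202] <- 1.4
    expect_length(callVstOutliers(low), 0)
})

test_that("planted dog duplications are recovered and clean tracks stay quiet", {
    flat <- function(gc) rep(1, length(gc))
    hits <- 0L
    for (seed in 1:10) {
        co <- generateCohort(testModel(), c(chr1 = 1.5e6), nDogs = 6,
                             nWolves = 6, nAncient = 1, seed = 100 + seed,
                             blockSize = 5e5)
        cnv <- cnvSpec("chr1", 600000, 624000, dogCN = 4, wolfCN = 2)
        co <- generateDepthProfiles(co, cnvs = cnv, meanDepth = 30,
                                    gcBiasCurve = flat, noiseSd = 0.05,
                                    seed = seed)
        cn <- estimateCopyNumber(gcCorrectDepth(cohortDepth(co),
                                                minBin = 2))
        out <- callVstOutliers(vstScan(cn))
        if (any(IRanges::overlapsAny(out, GRanges("chr1",
            IRanges(600001, 624000))))) hits <- hits + 1L
    }
    expect_gte(hits, 10 * 0.95 - 1e-9)

    # no planted CNV: no outlier regions on 500 windows x 10 seeds
    falseCalls <- 0L
    for (seed in 1:10) {
        co <- generateCohort(testModel(), c(chr1 = 1.5e6), nDogs = 6,
                             nWolves = 6, nAncient = 1, seed = 200 + seed,
                             blockSize = 5e5)
        co <- generateDepthProfiles(co, cnvs = NULL, meanDepth = 30,
                                    gcBiasCurve = flat, noiseSd = 0.05,
                                    seed = seed)
        cn <- estimateCopyNumber(gcCorrectDepth(cohortDepth(co),
                                                minBin = 2))
        falseCalls <- falseCalls + length(callVstOutliers(vstScan(cn)))
    }
    expect_lte(falseCalls, 1L)
})

test_that("depth tracks round-trip through bedGraph files", {
    co <- generateCohort(testModel(), c(chr1 = 9e4), nDogs = 2, nWolves = 2,
                         nAncient = 1, seed = 14)
    co <- generateDepthProfiles(co, meanDepth = 30, noiseSd = 0.02,
                                seed = 5)
    dir <- tempfile()
    paths <- writeDepthTracks(cohortDepth(co), dir)
    back <- readDepthTracks(paths[setdiff(names(paths), "gc")],
                            paths[["gc"]],
                            samplePanel(cohortVariants(co)))
    expect_equal(assay(back, "depth"), assay(cohortDepth(co), "depth"),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(rowRanges(back)$gc, rowRanges(cohortDepth(co))$gc,
                 tolerance = 1e-6)
})
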