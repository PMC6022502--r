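# small two-level ontology: root annotates 100 genes, child term A five
toyOntology <- function(nRoot = 100, nA = 5) {
    genes <- sprintf("g%03d", seq_len(nRoot))
    ann <- rbind(data.frame(gene = genes, term = "root",
                            stringsAsFactors = FALSE),
                 data.frame(gene = genes[seq_len(nA)], term = "A",
                            stringsAsFactors = FALSE))
    edges <- data.frame(child = "A", parent = "root",
                        stringsAsFactors = FALSE)
    buildOntology(ann, edges)
}

test_that("ontology construction propagates annotations and rejects cycles", {
    onto <- toyOntology()
    expect_setequal(onto$roots, "root")
    expect_length(onto$term2genes[["root"]], 100)
    expect_length(onto$term2genes[["A"]], 5)
    bad <- data.frame(child = c("A", "B"), parent = c("B", "A"))
    expect_error(buildOntology(data.frame(gene = "g", term = "A"), bad),
                 "cycle")
})

test_that("parent-child test equals the exact hypergeometric tail", {
    onto <- toyOntology()
    res <- parentChildTest(sprintf("g%03d", 1:5), onto)
    pA <- res$p[res$term == "A"]
    expect_equal(pA, 1 / choose(100, 5), tolerance = 1e-12)
    expect_equal(res$p[res$term == "root"], 1)

    # no test genes in the term: upper tail at k = 0 is 1
    res0 <- parentChildTest(sprintf("g%03d", 50:60), onto)
    expect_equal(res0$p[res0$term == "A"], 1)

    # exhaustive enumeration oracle on a random small DAG
    set.seed(6)
    genes <- sprintf("x%02d", 1:18)
    ann <- data.frame(gene = genes,
                      term = sample(c("t1", "t2", "t3"), 18, replace = TRUE))
    edges <- data.frame(child = c("t1", "t2", "t3"),
                        parent = c("rt", "rt", "t1"))
    ann <- rbind(ann, data.frame(gene = genes, term = "rt"))
    onto2 <- buildOntology(ann, edges)
    test <- sample(genes, 7)
    res2 <- parentChildTest(test, onto2)
    for (tm in c("t1", "t2", "t3")) {
        paU <- Reduce(union, onto2$term2genes[onto2$parents[[tm]]])
        N <- length(paU)
        K <- length(intersect(onto2$term2genes[[tm]], paU))
        n <- length(intersect(test, paU))
        k <- length(intersect(test, intersect(onto2$term2genes[[tm]], paU)))
        pExp <- sum(stats::dhyper(k:min(K, n), K, N - K, n))
        expect_equal(res2$p[res2$term == tm], pExp, tolerance = 1e-12)
    }
})

test_that("permutation p-values follow (X+1)/(N+1) with valid shuffles", {
    ann <- generateToyAnnotation(c(chr1 = 2e6, chr2 = 2e6), nGenes = 60,
                                 nTerms = 15, seed = 7)
    onto <- buildOntology(ann$annotation, ann$ontology)
    regions <- GRanges(c("chr1", "chr1", "chr2"),
                       IRanges(c(1e5, 9e5, 5e5), width = c(5e4, 8e4, 6e4)))
    GenomeInfoDb::seqlengths(regions) <- c(chr1 = 2e6, chr2 = 2e6)
    res <- suppressWarnings(
        permutationPvalues(regions, ann$genes, onto, N = 99, seed = 1))
    expect_true(all(res$pPerm == (res$Xperm + 1) / (res$N + 1)))
    expect_true(all(res$pPerm >= 1 / 100 & res$pPerm <= 1))
    expect_true(all(res$N == 99))
    expect_error(permutationPvalues(regions, ann$genes, onto, N = 0),
                 "N must be")
})

test_that("shuffles preserve chromosome and length with uniform placement", {
    r <- GRanges(c("chr1", "chr2"), IRanges(c(100, 200), width = c(500, 900)))
    GenomeInfoDb::seqlengths(r) <- c(chr1 = 1e5, chr2 = 2e5)
    set.seed(2)
    starts <- integer(2000)
    okChrom <- okWidth <- TRUE
    for (i in 1:2000) {
        s <- shuffleRegions(r)
        okChrom <- okChrom && identical(as.character(seqnames(s)),
                                        as.character(seqnames(r)))
        okWidth <- okWidth && identical(width(s), width(r))
        starts[i] <- start(s)[1]
    }
    expect_true(okChrom)
    expect_true(okWidth)
    # uniform starts: chi-square GOF on a two-bin partition
    half <- sum(starts <= (1e5 - 500) / 2)
    gof <- stats::chisq.test(c(half, 2000 - half), p = c(0.5, 0.5))
    expect_gt(gof$p.value, 0.01)

    # gap mask is honoured
    mask <- GRanges("chr1", IRanges(1, 9e4))
    set.seed(3)
    for (i in 1:20)
        expect_false(IRanges::overlapsAny(
            shuffleRegions(r[1], gapMask = mask), mask))
})

test_that("a random test set is enriched in ~5% of terms", {
    ann <- generateToyAnnotation(c(chr1 = 5e6), nGenes = 120, nTerms = 40,
                                 ontologyDepth = 4, seed = 9)
    onto <- buildOntology(ann$annotation, ann$ontology)
    tested <- 0L; sig <- 0L
    for (seed in 1:3) {
        regions <- GRanges("chr1",
            IRanges(sort(sample(4.5e6, 4)), width = 1e5))
        GenomeInfoDb::seqlengths(regions) <- c(chr1 = 5e6)
        set.seed(seed * 17)
        regions <- shuffleRegions(regions)
        res <- suppressWarnings(permutationPvalues(
            regions, ann$genes, onto, N = 199, seed = seed))
        tested <- tested + nrow(res)
        sig <- sig + sum(res$pPerm < 0.05)
    }
    # binomial 99% envelope around 5%
    ci <- stats::qbinom(c(0.005, 0.995), tested, 0.05)
    expect_gte(sig, ci[1])
    expect_lte(sig, ci[2])
})

test_that("enriched terms need significance plus multi-locus, multi-gene support", {
    res <- data.frame(term = c("a", "b", "c", "d"),
                      p = 0.001, Xperm = c(5, 5, 5, 400), N = 1000,
                      pPerm = c(0.01, 0.01, 0.01, 0.4),
                      nGenes = c(4, 5, 1, 6), nLoci = c(3, 1, 2, 4))
    kept <- filterEnrichedTerms(res)
    expect_identical(kept$term, "a")
})
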