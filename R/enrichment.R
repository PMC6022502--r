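#' Build a propagated ontology from edge and annotation tables
#'
#' Computes ancestor closures over the term DAG and propagates direct
#' gene-term annotations upward, so a gene annotated to a term counts for
#' every ancestor of that term.
#'
#' @param annotation data.frame(`gene`, `term`): direct annotations.
#' @param edges data.frame(`child`, `parent`) term DAG edges; terms absent
#'   from `edges` but present in `annotation` are treated as roots.
#' @return list of class "Ontology": `parents`, `ancestors`, `term2genes`
#'   (propagated), `roots`, `universe` (all annotated genes).
#' @export
buildOntology <- function(annotation, edges) {
    terms <- unique(c(annotation$term, edges$child, edges$parent))
    parents <- split(edges$parent, factor(edges$child, levels = terms))
    parents <- lapply(parents, unique)
    # topological order; detects cycles
    order <- character()
    state <- stats::setNames(rep(0L, length(terms)), terms)
    visit <- function(t) {
        if (state[[t]] == 1L) stop("ontology contains a cycle at ", t)
        if (state[[t]] == 2L) return(invisible())
        state[[t]] <<- 1L
        for (p in parents[[t]]) visit(p)
        state[[t]] <<- 2L
        order <<- c(order, t)
    }
    for (t in terms) visit(t)
    ancestors <- stats::setNames(vector("list", length(terms)), terms)
    for (t in order) {
        anc <- character()
        for (p in parents[[t]]) anc <- union(anc, c(p, ancestors[[p]]))
        ancestors[[t]] <- anc
    }
    t2g <- stats::setNames(vector("list", length(terms)), terms)
    for (i in seq_len(nrow(annotation))) {
        g <- annotation$gene[i]; tm <- annotation$term[i]
        for (t in c(tm, ancestors[[tm]]))
            t2g[[t]] <- c(t2g[[t]], g)
    }
    t2g <- lapply(t2g, unique)
    roots <- terms[lengths(parents[terms]) == 0]
    universe <- unique(annotation$gene)
    # precomputed integer index sets (into `universe`) make the
    # per-permutation parent-child test cheap
    t2i <- lapply(t2g, function(g) match(g, universe))
    paUnion <- stats::setNames(vector("list", length(terms)), terms)
    for (t in terms) {
        pa <- parents[[t]]
        if (length(pa))
            paUnion[[t]] <- sort(unique(unlist(t2i[pa], use.names = FALSE)))
    }
    structure(list(parents = parents, ancestors = ancestors,
                   term2genes = t2g, roots = roots, universe = universe,
                   term2idx = t2i, parentUnionIdx = paUnion),
              class = "Ontology")
}

#' Genes within a flank of candidate regions
#'
#' A gene is selected when its interval overlaps, or lies within `flank`
#' bp of, any region; the number of distinct supporting regions per gene
#' is recorded.
#'
#' @param regions GRanges of candidate regions.
#' @param genes GRanges with a `gene_id` column.
#' @param flank distance in bp (default 50 kb).
#' @return data.frame(`gene`, `nLoci`); zero rows when nothing intersects.
#' @export
genesNearRegions <- function(regions, genes, flank = 50000) {
    if (!length(regions) || !length(genes))
        return(data.frame(gene = character(), nLoci = integer(),
                          stringsAsFactors = FALSE))
    hit <- findOverlaps(genes, regions, maxgap = flank)
    if (!length(hit))
        return(data.frame(gene = character(), nLoci = integer(),
                          stringsAsFactors = FALSE))
    g <- genes$gene_id[S4Vectors::queryHits(hit)]
    n <- tapply(S4Vectors::subjectHits(hit), g,
                function(x) length(unique(x)))
    data.frame(gene = names(n), nLoci = as.integer(n),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Parent-child over-representation test
#'
#' For each term, the hypergeometric upper-tail probability of drawing at
#' least the observed number of the term's genes in the test set when
#' sampling from the genes annotated to the union of the term's parents
#' (the parent-child "union" variant). Root terms score 1 by construction;
#' terms whose parent union carries no genes are skipped.
#'
#' @param testGenes character vector of selected genes (subset of the
#'   universe).
#' @param ontology an [buildOntology()] result.
#' @param universe gene universe (default: all annotated genes).
#' @return data.frame(`term`, `p`, `k` genes of the term in the test set,
#'   `K` term genes in the parent union).
#' @export
parentChildTest <- function(testGenes, ontology, universe = NULL) {
    allGenes <- ontology$universe
    inUniv <- if (is.null(universe)) rep(TRUE, length(allGenes))
        else allGenes %in% universe
    inTest <- logical(length(allGenes))
    inTest[match(intersect(testGenes, allGenes), allGenes)] <- TRUE
    inTest <- inTest & inUniv
    terms <- names(ontology$term2idx)
    isRoot <- terms %in% ontology$roots
    p <- k <- K <- rep(NA_real_, length(terms))
    for (i in seq_along(terms)) {
        ti <- ontology$term2idx[[i]]
        ti <- ti[inUniv[ti]]
        if (isRoot[i]) {
            p[i] <- 1; k[i] <- sum(inTest[ti]); K[i] <- length(ti)
            next
        }
        pu <- ontology$parentUnionIdx[[i]]
        pu <- pu[inUniv[pu]]
        N <- length(pu)
        # propagation guarantees term genes lie inside the parent union
        Ki <- length(ti)
        if (N == 0 || Ki == 0) next
        n <- sum(inTest[pu])
        kk <- sum(inTest[ti])
        p[i] <- stats::phyper(kk - 1, Ki, N - Ki, n, lower.tail = FALSE)
        k[i] <- kk; K[i] <- Ki
    }
    ok <- !is.na(p)
    data.frame(term = terms[ok], p = p[ok], k = as.integer(k[ok]),
               K = as.integer(K[ok]), stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Uniform random shuffle of regions along their chromosomes
#'
#' Each interval is placed uniformly at random on its own chromosome with
#' its length preserved, avoiding an optional gap mask and overlap with
#' the other shuffled intervals (rejection sampling).
#'
#' @param regions GRanges; seqlengths must be set.
#' @param gapMask optional GRanges of excluded assembly gaps.
#' @param maxTries rejection-sampling cap per interval.
#' @return shuffled GRanges.
#' @export
shuffleRegions <- function(regions, gapMask = NULL, maxTries = 1000) {
    lens <- GenomeInfoDb::seqlengths(regions)
    chroms <- as.character(seqnames(regions))
    if (any(is.na(lens[unique(chroms)])))
        stop("seqlengths required for shuffling")
    w <- width(regions)
    maskS <- maskE <- maskC <- NULL
    if (!is.null(gapMask) && length(gapMask)) {
        maskS <- start(gapMask); maskE <- end(gapMask)
        maskC <- as.character(seqnames(gapMask))
    }
    newS <- integer(length(regions))
    for (i in seq_along(regions)) {
        L <- lens[[chroms[i]]]
        if (w[i] > L) stop("interval longer than its chromosome")
        done <- FALSE
        for (try in seq_len(maxTries)) {
            s <- floor(stats::runif(1, 0, L - w[i] + 1)) + 1
            e <- s + w[i] - 1
            bad <- FALSE
            if (!is.null(maskS)) {
                m <- maskC == chroms[i]
                bad <- any(m & maskS <= e & maskE >= s)
            }
            if (!bad && i > 1) {
                prev <- seq_len(i - 1)
                m <- chroms[prev] == chroms[i]
                bad <- any(m & newS[prev] <= e &
                           (newS[prev] + w[prev] - 1) >= s)
            }
            if (!bad) { done <- TRUE; newS[i] <- s; break }
        }
        if (!done) stop("could not place shuffled interval")
    }
    out <- regions
    IRanges::ranges(out) <- IRanges(newS, width = w)
    out
}

#' Permutation p-value with pseudocount
#'
#' `(Xperm + 1) / (N + 1)`: one is added to numerator and denominator so
#' no term reports exactly 0 or an unattainable p-value.
#' @param Xperm number of permutations at or beyond the observed score.
#' @param N number of permutations.
#' @return p-value in `[1/(N+1), 1]`.
#' @export
permPValue <- function(Xperm, N) {
    stopifnot(all(N >= 1), all(Xperm >= 0), all(Xperm <= N))
    (Xperm + 1) / (N + 1)
}

#' Permutation-calibrated enrichment p-values
#'
#' Computes the observed parent-child p-value per term for the genes
#' within `flank` bp of the candidate regions, then repeats the test on
#' `N` random shuffles of the regions. `X_perm` counts permutations whose
#' p-value is less than or equal to the observed one (ties count), and
#' `p_perm = (X_perm + 1) / (N + 1)`, bounded in [1/(N+1), 1].
#'
#' @param regions GRanges of candidate loci (seqlengths set).
#' @param genes GRanges with `gene_id`.
#' @param ontology a [buildOntology()] result.
#' @param N number of permutations (default 1000).
#' @param seed integer seed.
#' @param flank gene-region intersection distance (bp).
#' @param gapMask optional GRanges excluded from shuffling.
#' @param universe optional gene universe.
#' @return data.frame(`term`, `p`, `Xperm`, `N`, `pPerm`, `nGenes`,
#'   `nLoci`).
#' @export
permutationPvalues <- function(regions, genes, ontology, N = 1000, seed = 1,
                               flank = 50000, gapMask = NULL,
                               universe = NULL) {
    if (N < 1) stop("N must be >= 1")
    obsGenes <- genesNearRegions(regions, genes, flank)
    obs <- parentChildTest(obsGenes$gene, ontology, universe)
    if (is.null(obs) || !nrow(obs))
        return(data.frame(term = character(), p = numeric(),
                          Xperm = integer(), N = integer(),
                          pPerm = numeric(), nGenes = integer(),
                          nLoci = integer(), stringsAsFactors = FALSE))
    # supporting loci per term: distinct regions within flank of >= 1 term gene
    hit <- findOverlaps(genes, regions, maxgap = flank)
    gOf <- split(S4Vectors::subjectHits(hit),
                 genes$gene_id[S4Vectors::queryHits(hit)])
    nLoci <- vapply(obs$term, function(t) {
        tg <- intersect(ontology$term2genes[[t]], obsGenes$gene)
        length(unique(unlist(gOf[tg], use.names = FALSE)))
    }, integer(1))
    nGenes <- vapply(obs$term, function(t)
        length(intersect(ontology$term2genes[[t]], obsGenes$gene)),
        integer(1))
    set.seed(seed)
    X <- stats::setNames(integer(nrow(obs)), obs$term)
    # flat vectors make the per-permutation gene lookup cheap
    geneCh <- as.character(seqnames(genes))
    geneS <- start(genes); geneE <- end(genes); geneId <- genes$gene_id
    fastNear <- function(regCh, regS, regE) {
        hit <- logical(length(geneId))
        for (j in seq_along(regCh)) {
            hit <- hit | (geneCh == regCh[j] & geneS <= regE[j] + flank &
                          geneE >= regS[j] - flank)
        }
        geneId[hit]
    }
    for (b in seq_len(N)) {
        sh <- shuffleRegions(regions, gapMask)
        pg <- fastNear(as.character(seqnames(sh)), start(sh), end(sh))
        pp <- parentChildTest(pg, ontology, universe)
        pv <- stats::setNames(rep(1, nrow(obs)), obs$term)
        if (!is.null(pp) && nrow(pp)) {
            common <- intersect(obs$term, pp$term)
            pv[common] <- pp$p[match(common, pp$term)]
        }
        X <- X + as.integer(pv <= obs$p)
    }
    data.frame(term = obs$term, p = obs$p, Xperm = as.integer(X),
               N = as.integer(N), pPerm = permPValue(X, N),
               nGenes = nGenes, nLoci = nLoci, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Filter enriched terms
#'
#' Keeps terms with `pPerm < alpha` that are supported by more than one
#' locus and more than one gene, removing enrichments that could arise
#' from a single clustered locus or a single multiply-hit gene.
#'
#' @param results data.frame from [permutationPvalues()].
#' @param alpha significance cutoff on `pPerm` (default 0.05).
#' @return the filtered data.frame.
#' @export
filterEnrichedTerms <- function(results, alpha = 0.05) {
    results[results$pPerm < alpha & results$nLoci >= 2 &
                results$nGenes >= 2, , drop = FALSE]
}
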