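#' Write windows or regions as TSV (0-based half-open starts)
#' @param gr GRanges with metadata columns.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeWindowTsv <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1, end = end(gr),
                     as.data.frame(mcols(gr)), stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write regions as BED (0-based half-open)
#' @param gr GRanges; an optional `name` column becomes the BED name.
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
writeRegionsBed <- function(gr, path) {
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- rep(".", length(gr))
    df <- data.frame(as.character(seqnames(gr)), start(gr) - 1, end(gr), nm)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write per-sample depth tracks and the GC track as bedGraph
#' @param dp A [DepthProfiles-class].
#' @param dir output directory (created if needed).
#' @return named vector of written depth paths plus a `gc` entry,
#'   invisibly.
#' @export
writeDepthTracks <- function(dp, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    win <- granges(rowRanges(dp))
    d <- assay(dp, "depth")
    paths <- character()
    for (s in colnames(d)) {
        gr <- win
        mcols(gr)$score <- unname(d[, s])
        p <- file.path(dir, paste0(s, ".depth.bedgraph"))
        rtracklayer::export(gr, p, format = "bedGraph")
        paths[s] <- p
    }
    gc <- win
    mcols(gc)$score <- rowRanges(dp)$gc
    gcPath <- file.path(dir, "gc.bedgraph")
    rtracklayer::export(gc, gcPath, format = "bedGraph")
    invisible(c(paths, gc = gcPath))
}

#' Genotype matrix for a candidate region
#'
#' Rows are samples grouped by population (dogs, then wolves, then
#' ancients when supplied), columns the region's SNPs in positional
#' order; cells are 0 (hom-ref), 1 (het) and 2 (hom-alt).
#'
#' @param x A [VariantTable-class].
#' @param region length-1 GRanges.
#' @param ancientGt optional ancient dosage matrix aligned with `x`'s
#'   rows.
#' @param path optional path; when given the matrix is written as TSV.
#' @return integer matrix samples x SNPs (invisibly when written).
#' @export
genotypeMatrix <- function(x, region, ancientGt = NULL, path = NULL) {
    stopifnot(length(region) == 1)
    i <- which(suppressWarnings(
        IRanges::overlapsAny(rowRanges(x), region)))
    if (!length(i)) warning("region contains no SNPs; empty matrix")
    ord <- order(match(colData(x)$population, c("dog", "wolf", "ancient")))
    m <- t(genotypes(x)[i, ord, drop = FALSE])
    colnames(m) <- if (length(i))
        paste0(as.character(seqnames(rowRanges(x)))[i], ":",
               start(rowRanges(x))[i]) else character()
    if (!is.null(ancientGt)) {
        a <- t(ancientGt[i, , drop = FALSE])
        colnames(a) <- colnames(m)
        m <- rbind(m, a)
    }
    if (!is.null(path)) {
        utils::write.table(m, path, sep = "\t", quote = FALSE,
                           col.names = NA)
        return(invisible(m))
    }
    m
}
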