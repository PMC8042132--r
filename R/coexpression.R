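## Co-expression front end: quantile normalization across samples, a full
## gene-gene Pearson correlation matrix, and per-gene K-nearest-neighbor
## extraction. Neighbors are ranked by signed r (most positively
## correlated), the reading of "most highly correlated" used throughout;
## rank by |r| is available via `absolute = TRUE`.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common reference distribution: the
#' per-rank mean of the sorted sample vectors. Ties within a sample
#' receive the mean of the reference values at the tied ranks, so tied
#' inputs stay tied and each sample's rank order is preserved.
#'
#' @param x genes x samples matrix or SummarizedExperiment, no missing
#'   values, at least two samples.
#' @return Same container type as the input, normalized.
#' @examples
#' m <- matrix(c(5, 1, 3, 2, 4, 6), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' quantileNormalize(m)  # reference is c(1.5, 3.5, 5.5)
#' @export
quantileNormalize <- function(x) {
    wasSE <- is(x, "SummarizedExperiment")
    m <- .exprMatrix(x)
    if (ncol(m) < 2L)
        stop("quantile normalization needs at least 2 samples")
    ref <- rowMeans(apply(m, 2L, sort))
    out <- apply(m, 2L, function(v) {
        ## average the reference values over each tied group of ranks
        rk <- rank(v, ties.method = "min")
        cnt <- table(rk)
        grpMean <- vapply(as.integer(names(cnt)), function(r0)
            mean(ref[r0:(r0 + cnt[[as.character(r0)]] - 1L)]), numeric(1L))
        grpMean[match(rk, as.integer(names(cnt)))]
    })
    dimnames(out) <- dimnames(m)
    if (wasSE) .asSE(out) else out
}

#' Gene-gene Pearson correlation matrix
#'
#' Sample Pearson coefficient for every gene pair. Genes with zero
#' variance (undefined r) are assigned r = 0 against all partners and
#' reported in the `zeroVariance` slot rather than propagating NaN, so
#' the matrix is total and neighbor extraction is deterministic.
#'
#' @param x genes x samples matrix or SummarizedExperiment with at least
#'   3 samples.
#' @return A [CorrelationMatrix-class] object.
#' @export
correlationMatrix <- function(x) {
    m <- .exprMatrix(x)
    if (ncol(m) < 3L)
        stop("correlation needs at least 3 samples")
    sds <- apply(m, 1L, stats::sd)
    flat <- rownames(m)[sds == 0]
    r <- suppressWarnings(stats::cor(t(m)))
    r[is.na(r)] <- 0
    diag(r) <- 1
    r <- (r + t(r)) / 2  # enforce exact symmetry against fp noise
    new("CorrelationMatrix", r = r, zeroVariance = flat)
}

#' Extract each gene's K most-correlated neighbors
#'
#' For every gene, the `k` partners with the largest correlation (self
#' excluded). Exact ties in r are broken by ascending lexicographic gene
#' id; lists are truncated to `n_genes - 1` when `k` exceeds it.
#'
#' @param cmat a [CorrelationMatrix-class] object.
#' @param k neighbor count (default 40, the usual compendium setting).
#' @param absolute rank by |r| instead of signed r.
#' @return A [NeighborList-class] object.
#' @export
knnNeighbors <- function(cmat, k = 40L, absolute = FALSE) {
    if (k < 1L) stop("k must be >= 1")
    r <- cmat@r
    genes <- rownames(r)
    kEff <- min(as.integer(k), length(genes) - 1L)
    nb <- lapply(genes, function(g) {
        rv <- r[g, setdiff(genes, g)]
        key <- if (absolute) abs(rv) else rv
        ord <- order(-key, names(rv))[seq_len(kEff)]
        data.frame(neighbor_id = names(rv)[ord], r = unname(rv[ord]),
                   stringsAsFactors = FALSE)
    })
    names(nb) <- genes
    new("NeighborList", neighbors = nb, k = as.integer(k))
}

#' Write a neighbor list as TSV
#'
#' Columns: `gene_id`, `rank`, `neighbor_id`, `r`.
#'
#' @param x a [NeighborList-class] object.
#' @param path file path.
#' @export
writeNeighbors <- function(x, path) {
    rows <- unlist(lapply(names(x@neighbors), function(g) {
        nb <- x@neighbors[[g]]
        paste(g, seq_len(nrow(nb)), nb$neighbor_id, .fmtNum(nb$r),
              sep = "\t")
    }))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("gene_id\trank\tneighbor_id\tr", rows), con, sep = "\n")
    invisible(path)
}
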