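## Robust expression profiling: genes ranked within a tissue panel by the
## modified Z-score (Iglewicz-Hoaglin form) of their mean expression,
## plus cross-gene abundance ratios.

#' Modified Z-score
#'
#' `z_i = 0.6745 * (x_i - median(x)) / MAD(x)` with
#' `MAD = median(|x - median(x)|)` (unscaled). When MAD is 0 (at least
#' half the values identical) this is undefined; the default is an error
#' directing the caller to the mean-absolute-deviation fallback
#' `z_i = 0.7979 * (x_i - median(x)) / meanAD(x)`, applied only on
#' explicit request via `fallback = TRUE`.
#'
#' @param x numeric vector of at least 3 values.
#' @param fallback use the mean-absolute-deviation scale when MAD = 0.
#' @return Numeric vector of modified Z-scores.
#' @examples
#' modifiedZ(c(1, 2, 3, 4, 100))  # z for 100 is 0.6745 * 97
#' @export
modifiedZ <- function(x, fallback = FALSE) {
    if (length(x) < 3L) stop("need at least 3 values")
    if (any(!is.finite(x))) stop("values must be finite")
    med <- stats::median(x)
    mad0 <- stats::median(abs(x - med))
    if (mad0 > 0) return(0.6745 * (x - med) / mad0)
    if (!fallback)
        stop("MAD is 0 (at least half the values are identical); ",
             "rerun with fallback = TRUE to use the mean-absolute-",
             "deviation scale")
    meanAD <- mean(abs(x - med))
    if (meanAD == 0) stop("all values identical; no scale available")
    0.7979 * (x - med) / meanAD
}

#' Rank genes by robust standardized mean expression
#'
#' Summarizes each gene as its mean expression across the panel's
#' samples, then standardizes those means across genes with the modified
#' Z-score. Genes with z above `cutoff` are flagged as highly expressed
#' relative to the panel median. `summarization = "zPerSampleMean"` instead
#' standardizes within each sample and averages the per-sample z across
#' samples (the alternative summarization order, exposed for
#' comparison).
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param cutoff z threshold for the `high` flag (default 3.5, the usual
#'   robust-outlier convention).
#' @param fallback passed to [modifiedZ()].
#' @param summarization `"meanThenZ"` (default) or `"zPerSampleMean"`.
#' @return data.frame with columns `gene_id`, `mean_expr`, `modified_z`,
#'   `high`, sorted by `modified_z` descending.
#' @export
profileExpression <- function(expr, cutoff = 3.5, fallback = FALSE,
                              summarization = c("meanThenZ",
                                                "zPerSampleMean")) {
    summarization <- match.arg(summarization)
    m <- .exprMatrix(expr)
    means <- rowMeans(m)
    z <- if (summarization == "meanThenZ") modifiedZ(means, fallback = fallback)
         else rowMeans(apply(m, 2L, modifiedZ, fallback = fallback))
    res <- data.frame(gene_id = rownames(m), mean_expr = unname(means),
                      modified_z = unname(z), high = unname(z > cutoff),
                      stringsAsFactors = FALSE)
    res <- res[order(-res$modified_z, res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Abundance ratio of two genes over a sample group
#'
#' Ratio of group-mean expression of `geneA` to `geneB`. Use this on a
#' linear scale (e.g. TPM); on log2 data a ratio of means is not a fold
#' change.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param geneA,geneB gene ids present in `expr`.
#' @param samples sample ids of the group; default all samples.
#' @return list with `ratio` (numeric) and `label` (the "~x.y" rounded
#'   display form).
#' @export
abundanceRatio <- function(expr, geneA, geneB, samples = NULL) {
    m <- .exprMatrix(expr)
    for (g in c(geneA, geneB))
        if (!g %in% rownames(m)) stop("gene '", g, "' not in matrix")
    if (is.null(samples)) samples <- colnames(m)
    if (!length(samples)) stop("sample group is empty")
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) stop("unknown sample '", missing[1L], "'")
    denom <- mean(m[geneB, samples])
    if (denom <= 0) stop("denominator gene '", geneB,
                         "' has non-positive group mean")
    ratio <- mean(m[geneA, samples]) / denom
    list(ratio = ratio, label = sprintf("~%.1f", ratio))
}
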