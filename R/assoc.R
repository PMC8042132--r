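## Strain-panel association screen: plain Pearson correlation of each
## gene's expression against each phenotype, two-sided p from the t
## transform, significance at raw p < alpha. No multiple-testing
## correction is applied at this stage — the screen reports raw p-values
## by design (correction lives in the enrichment stage); output headers
## say so.

#' Pearson association between two vectors
#'
#' Pairwise deletion of missing values, then the sample Pearson
#' coefficient and the two-sided p-value of
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' `|r| = 1` returns p = 0. Zero variance in either vector is an error —
#' a trait screen must surface degenerate traits, not silently report
#' r = 0.
#'
#' @param x,y numeric vectors of equal length with at least 3 paired
#'   non-missing values.
#' @return list with elements `r`, `n`, `p`.
#' @examples
#' pearsonAssoc(1:10, c(2:10, 12))
#' @export
pearsonAssoc <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) stop("need at least 3 paired non-missing values, got ", n)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in input vector; degenerate trait or gene")
    r <- stats::cor(x, y)
    if (abs(r) > 1) r <- sign(r)  # guard against fp overshoot
    if (1 - r^2 < 1e-14) {        # exact linear dependence
        p <- 0
    } else {
        t <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    list(r = r, n = n, p = p)
}

#' Screen gene expression against a phenotype panel
#'
#' One Pearson association per (gene, trait) pair over the shared
#' samples, with pairwise deletion of missing trait values. Traits with
#' fewer than 3 usable values (or zero variance) are skipped and listed
#' in the `skipped` attribute rather than aborting the screen.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param traits a [TraitTable-class] object (samples x traits).
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return data.frame with columns `gene_id`, `trait_id`, `n`, `r`, `p`,
#'   `significant`, sorted by p ascending (ties by gene id then trait
#'   id); attribute `skipped` lists unusable traits.
#' @export
screenAssociations <- function(expr, traits, alpha = 0.05) {
    m <- .exprMatrix(expr)
    tv <- traitValues(traits)
    shared <- intersect(colnames(m), rownames(tv))
    if (length(shared) < 3L)
        stop("expression and trait tables share ", length(shared),
             " samples; need at least 3")
    m <- m[, shared, drop = FALSE]
    tv <- tv[shared, , drop = FALSE]
    skipped <- character()
    out <- vector("list", ncol(tv) * nrow(m))
    k <- 0L
    for (tr in colnames(tv)) {
        y <- tv[, tr]
        if (sum(is.finite(y)) < 3L ||
            stats::sd(y[is.finite(y)]) %in% c(0, NA)) {
            skipped <- c(skipped, tr)
            next
        }
        for (g in rownames(m)) {
            a <- tryCatch(pearsonAssoc(m[g, ], y), error = function(e) NULL)
            if (is.null(a)) next
            k <- k + 1L
            out[[k]] <- data.frame(gene_id = g, trait_id = tr, n = a$n,
                                   r = a$r, p = a$p,
                                   significant = a$p < alpha,
                                   stringsAsFactors = FALSE)
        }
    }
    res <- if (k) do.call(rbind, out[seq_len(k)]) else
        data.frame(gene_id = character(), trait_id = character(),
                   n = integer(), r = numeric(), p = numeric(),
                   significant = logical(), stringsAsFactors = FALSE)
    res <- res[order(res$p, res$gene_id, res$trait_id), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "skipped") <- skipped
    res
}

#' Write an association screen as TSV
#'
#' Columns `gene_id`, `trait_id`, `n`, `r`, `p`, `significant`. The
#' header comment records that p-values are raw (uncorrected).
#'
#' @param x data.frame from [screenAssociations()].
#' @param path file path.
#' @export
writeAssociations <- function(x, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("# raw (uncorrected) two-sided Pearson p-values",
                 "gene_id\ttrait_id\tn\tr\tp\tsignificant",
                 if (nrow(x)) paste(x$gene_id, x$trait_id, x$n,
                                    .fmtNum(x$r), .fmtNum(x$p),
                                    tolower(x$significant), sep = "\t")),
               con, sep = "\n")
    invisible(path)
}
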