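## Overrepresentation analysis of a gene list against a gene-set
## collection: hypergeometric upper-tail p, enrichment ratio
## (observed / expected overlap), Benjamini-Hochberg adjustment. Sets
## failing the minimum-overlap filter are removed BEFORE adjustment
## (which changes the number of tests m), matching the convention of the
## usual web ORA tools.

#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` genes of a `K`-gene set when
#' `nQuery` genes are drawn without replacement from an `N`-gene
#' universe.
#'
#' @param k observed overlap.
#' @param nQuery query size.
#' @param K set size.
#' @param N universe size.
#' @return The p-value.
#' @examples
#' hypergeomUpper(4, 4, 5, 10)  # 5/210
#' @export
hypergeomUpper <- function(k, nQuery, K, N) {
    if (K > N || nQuery > N || k > min(nQuery, K) || k < 0)
        stop("inconsistent counts: k=", k, ", nQuery=", nQuery,
             ", K=", K, ", N=", N)
    stats::phyper(k - 1, K, N - K, nQuery, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, returned in
#' the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Overrepresentation analysis
#'
#' Every set is first intersected with the universe; sets whose overlap
#' with the query is below `minOverlap` are excluded before BH
#' adjustment. `expected = |query| * set_size / N`;
#' `enrichment_ratio = overlap / expected`. Significance requires
#' adjusted p below `alphaAdj`.
#'
#' @param query gene ids (subset of `universe`).
#' @param sets a [GeneSetCollection-class] object.
#' @param universe background gene ids.
#' @param minOverlap minimum query-set overlap for a set to be tested
#'   (default 5).
#' @param alphaAdj adjusted-p significance threshold (default 0.05).
#' @param top optional cap on the number of reported sets (by adjusted
#'   p); `NULL` reports all tested sets.
#' @return data.frame with columns `set_name`, `overlap`, `set_size`,
#'   `expected`, `enrichment_ratio`, `p`, `p_adj`, `significant`, sorted
#'   by p_adj ascending then enrichment_ratio descending. Empty (not an
#'   error) when no set passes the overlap filter.
#' @export
ora <- function(query, sets, universe, minOverlap = 5L, alphaAdj = 0.05,
                top = NULL) {
    query <- unique(query)
    missing <- setdiff(query, universe)
    if (length(missing))
        stop("query gene '", missing[1L], "' is not in the universe")
    N <- length(unique(universe))
    sl <- lapply(geneSets(sets), intersect, universe)
    sl <- sl[lengths(sl) > 0L]
    overlap <- vapply(sl, function(s) length(intersect(s, query)),
                      integer(1L))
    keep <- overlap >= minOverlap
    sl <- sl[keep]; overlap <- overlap[keep]
    if (!length(sl))
        return(data.frame(set_name = character(), overlap = integer(),
                          set_size = integer(), expected = numeric(),
                          enrichment_ratio = numeric(), p = numeric(),
                          p_adj = numeric(), significant = logical(),
                          stringsAsFactors = FALSE))
    K <- lengths(sl)
    p <- mapply(hypergeomUpper, overlap, length(query), K,
                MoreArgs = list(N = N))
    res <- data.frame(set_name = names(sl), overlap = unname(overlap),
                      set_size = unname(K),
                      expected = length(query) * unname(K) / N,
                      stringsAsFactors = FALSE)
    res$enrichment_ratio <- res$overlap / res$expected
    res$p <- unname(p)
    res$p_adj <- bhAdjust(res$p)
    res$significant <- res$p_adj < alphaAdj
    res <- res[order(res$p_adj, -res$enrichment_ratio, res$set_name), ,
               drop = FALSE]
    if (!is.null(top)) res <- utils::head(res, top)
    rownames(res) <- NULL
    res
}

#' Write ORA results as TSV
#'
#' Columns `set_name`, `overlap`, `set_size`, `expected`,
#' `enrichment_ratio`, `p`, `p_adj`, `significant`.
#'
#' @param x data.frame from [ora()].
#' @param path file path.
#' @export
writeEnrichment <- function(x, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(paste("set_name", "overlap", "set_size", "expected",
                       "enrichment_ratio", "p", "p_adj", "significant",
                       sep = "\t"),
                 if (nrow(x)) paste(x$set_name, x$overlap, x$set_size,
                                    .fmtNum(x$expected),
                                    .fmtNum(x$enrichment_ratio),
                                    .fmtNum(x$p), .fmtNum(x$p_adj),
                                    tolower(x$significant), sep = "\t")),
               con, sep = "\n")
    invisible(path)
}
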