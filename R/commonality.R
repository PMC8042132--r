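## Commonality scoring: what does a query gene set share in the
## literature network? For each concept the number of query genes with a
## literature connection to it ("shared rels"), the ratio of that count
## to its expectation under a degree-proportional chance model
## ("Obs/Exp"), and their product ("Score") — the Score balances how
## unusual the connection count is against how much evidence backs it.
## The null expectation for a concept connected to d of the N universe
## genes, under uniform draws of a |query|-gene set, is |query| * d / N
## (the hypergeometric mean).

#' Per-concept gene-degree table
#'
#' For every non-gene concept in the network, the number of universe
#' genes it is connected to (its gene-degree `d`), together with the
#' universe size `N`. Edges to genes outside the universe do not count.
#'
#' @param net a [CooccurrenceNetwork-class] object.
#' @param universe character vector of gene term ids defining the
#'   background.
#' @return data.frame with columns `concept`, `concept_type`, `d`, plus
#'   attribute `N = length(universe)`. Concepts with no gene edges appear
#'   with `d = 0`.
#' @export
conceptDegrees <- function(net, universe) {
    if (!length(universe)) stop("universe must be nonempty")
    nodes <- net@nodes
    concepts <- nodes[nodes$concept_type != "gene", , drop = FALSE]
    e <- net@edges
    inU <- function(x) x %in% universe
    d <- vapply(concepts$term_id, function(cc) {
        sum((e$term_a == cc & inU(e$term_b)) |
            (e$term_b == cc & inU(e$term_a)))
    }, integer(1L))
    out <- data.frame(concept = concepts$term_id,
                      concept_type = concepts$concept_type,
                      d = unname(d), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "N") <- length(universe)
    out
}

#' Score literature commonalities of a query gene set
#'
#' For each concept with at least `minShared` query-gene connections:
#' `shared_rels` = number of query genes with an edge to the concept;
#' `expected` = `|query| * d / N` under uniform query draws from the
#' universe; `obs_exp = shared_rels / expected`; `score = shared_rels *
#' obs_exp`. Concepts with no universe-gene connections are never
#' reported. Results are sorted by score descending, ties by shared_rels
#' descending then term id ascending. Edge weights are ignored
#' (presence/absence only) unless `wMin` raises the minimum count for an
#' edge to qualify as a connection.
#'
#' @param query gene term ids (must be a subset of `universe`).
#' @param net a [CooccurrenceNetwork-class] object.
#' @param universe background gene term ids.
#' @param minShared minimum shared_rels to report (default 2: a single
#'   link carries no enrichment information).
#' @param wMin minimum co-occurrence weight for an edge to count
#'   (default 1).
#' @param conceptTypes optional concept types to keep (e.g. `"disease"`).
#' @param keywords optional regular expression; only concepts whose term
#'   id matches are kept (the analogue of manually selecting, say,
#'   cardiovascular concepts from the full ranking).
#' @return data.frame with columns `concept`, `concept_type`,
#'   `shared_rels`, `expected`, `obs_exp`, `score`.
#' @examples
#' ## |query| = 40 of N = 100 genes, concept linked to d = 10, 8 shared:
#' ## expected = 4, obs_exp = 2, score = 16
#' @export
scoreCommonalities <- function(query, net, universe, minShared = 2L,
                               wMin = 1L, conceptTypes = NULL,
                               keywords = NULL) {
    if (!length(query)) stop("query must contain at least one gene")
    missing <- setdiff(query, universe)
    if (length(missing))
        stop("query gene '", missing[1L], "' is not in the universe")
    e <- net@edges
    e <- e[e$weight >= wMin, , drop = FALSE]
    netU <- new("CooccurrenceNetwork", nodes = net@nodes, edges = e)
    deg <- conceptDegrees(netU, universe)
    N <- attr(deg, "N")
    shared <- vapply(deg$concept, function(cc) {
        sum((e$term_a == cc & e$term_b %in% query) |
            (e$term_b == cc & e$term_a %in% query))
    }, integer(1L))
    keep <- shared >= minShared & deg$d >= 1L
    res <- data.frame(concept = deg$concept[keep],
                      concept_type = deg$concept_type[keep],
                      shared_rels = unname(shared[keep]),
                      stringsAsFactors = FALSE)
    res$expected <- length(query) * deg$d[keep] / N
    res$obs_exp <- res$shared_rels / res$expected
    res$score <- res$shared_rels * res$obs_exp
    if (!is.null(conceptTypes))
        res <- res[res$concept_type %in% conceptTypes, , drop = FALSE]
    if (!is.null(keywords))
        res <- res[grepl(keywords, res$concept, ignore.case = TRUE), ,
                   drop = FALSE]
    res <- res[order(-res$score, -res$shared_rels, res$concept), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Guilt-by-association commonality profile for one gene
#'
#' Applies [scoreCommonalities()] to the gene's co-expression neighbor
#' set: the literature commonalities of a gene's most-correlated genes
#' are its predicted functions. The input gene itself is excluded from
#' the query set.
#'
#' @param gene a gene term id present in `neighbors`.
#' @param neighbors a [NeighborList-class] object.
#' @param net a [CooccurrenceNetwork-class] object.
#' @param universe background gene term ids.
#' @param minShared,wMin,conceptTypes,keywords passed to
#'   [scoreCommonalities()].
#' @return data.frame as from [scoreCommonalities()]; empty when the
#'   neighbor genes have no qualifying literature connections.
#' @export
gammaProfile <- function(gene, neighbors, net, universe, minShared = 2L,
                         wMin = 1L, conceptTypes = NULL, keywords = NULL) {
    nb <- neighborsOf(neighbors, gene)
    query <- setdiff(nb$neighbor_id, gene)
    scoreCommonalities(query, net, universe, minShared = minShared,
                       wMin = wMin, conceptTypes = conceptTypes,
                       keywords = keywords)
}

#' Write commonality profiles as TSV
#'
#' Columns: `query_gene`, `concept`, `concept_type`, `shared_rels`,
#' `expected`, `obs_exp`, `score`.
#'
#' @param profiles named list of data.frames from [gammaProfile()] /
#'   [scoreCommonalities()], named by query gene.
#' @param path file path.
#' @export
writeCommonalities <- function(profiles, path) {
    rows <- unlist(lapply(names(profiles), function(g) {
        p <- profiles[[g]]
        if (!nrow(p)) return(character())
        paste(g, p$concept, p$concept_type, p$shared_rels,
              .fmtNum(p$expected), .fmtNum(p$obs_exp), .fmtNum(p$score),
              sep = "\t")
    }))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(paste("query_gene", "concept", "concept_type",
                       "shared_rels", "expected", "obs_exp", "score",
                       sep = "\t"), rows), con, sep = "\n")
    invisible(path)
}
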