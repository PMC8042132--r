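## Literature mining: thesaurus-driven term recognition in abstracts and
## the document-level co-occurrence network built from it. Matching is
## dictionary-only — case-insensitive, at token boundaries, longest match
## wins — with no stemming or stop-word logic.

#' Recognize thesaurus terms in a document
#'
#' Tokenizes the text (splitting on non-alphanumeric characters, keeping
#' internal hyphens) and scans left to right, preferring the longest
#' surface form starting at each token; tokens consumed by a match are
#' unavailable to shorter overlapping matches. Each term is reported at
#' most once per document however often its surface forms repeat.
#'
#' @param text a single document string.
#' @param thes a [Thesaurus-class] object.
#' @return Character vector of recognized term ids (sorted, unique);
#'   empty text yields an empty set.
#' @examples
#' th <- thesaurus(
#'     data.frame(term_id = c("T2", "T3"),
#'                concept_type = c("gene", "gene"),
#'                canonical = c("integrin", "integrin alpha 9")),
#'     list(T2 = "integrin", T3 = "integrin alpha 9"))
#' recognizeTerms("integrin alpha 9 binds", th)  # "T3" only
#' @export
recognizeTerms <- function(text, thes) {
    toks <- tolower(tokenize(text))
    n <- length(toks)
    if (!n) return(character())
    map <- thes@surfaceMap
    maxLen <- max(vapply(strsplit(names(map), " ", fixed = TRUE), length,
                         integer(1L)))
    found <- character()
    i <- 1L
    while (i <= n) {
        hit <- FALSE
        for (len in seq.int(min(maxLen, n - i + 1L), 1L)) {
            key <- paste(toks[i:(i + len - 1L)], collapse = " ")
            id <- unname(map[key])
            if (!is.na(id)) {
                found <- c(found, id)
                i <- i + len
                hit <- TRUE
                break
            }
        }
        if (!hit) i <- i + 1L
    }
    sort(unique(found))
}

#' Build the literature co-occurrence network
#'
#' Runs term recognition over every document and counts, for each
#' unordered term pair, the number of documents in which both were
#' recognized. Terms recognized at least once become nodes even when they
#' never co-occur (isolated nodes are allowed); there are no self-loops.
#' The result is independent of document order.
#'
#' @param corp a [Corpus-class] object.
#' @param thes a [Thesaurus-class] object.
#' @return A [CooccurrenceNetwork-class] object.
#' @export
buildNetwork <- function(corp, thes) {
    types <- conceptTypes(thes)
    docTerms <- lapply(seq_len(nDocs(corp)),
                       function(i) recognizeTerms(corp@texts[i], thes))
    seen <- as.character(sort(unique(unlist(docTerms))))
    docCount <- vapply(seen, function(t)
        sum(vapply(docTerms, function(d) t %in% d, logical(1L))),
        integer(1L))
    pairKeys <- unlist(lapply(docTerms, function(d) {
        if (length(d) < 2L) return(character())
        cmb <- utils::combn(d, 2L)  # d is sorted, so term_a < term_b
        paste(cmb[1L, ], cmb[2L, ], sep = "\t")
    }))
    if (length(pairKeys)) {
        tab <- table(pairKeys)
        parts <- strsplit(names(tab), "\t", fixed = TRUE)
        edges <- data.frame(
            term_a = vapply(parts, `[`, character(1L), 1L),
            term_b = vapply(parts, `[`, character(1L), 2L),
            weight = as.integer(tab),
            stringsAsFactors = FALSE)
        edges <- edges[order(edges$term_a, edges$term_b), , drop = FALSE]
        rownames(edges) <- NULL
    } else {
        edges <- data.frame(term_a = character(), term_b = character(),
                            weight = integer(), stringsAsFactors = FALSE)
    }
    nodes <- data.frame(term_id = seen,
                        concept_type = unname(types[seen]),
                        doc_count = unname(docCount),
                        stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
    new("CooccurrenceNetwork", nodes = nodes, edges = edges)
}
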