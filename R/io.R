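## File-based stage boundaries: every artifact has a strict plain-text
## reader/writer pair so any stage can be inspected or rerun in isolation.
## TSV is tab-separated UTF-8 with Unix newlines; corpora are JSONL; gene
## sets are GMT. Numeric round-trips are stable to 12 significant digits.

.splitTSV <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    strsplit(lines, "\t", fixed = TRUE)
}

.fmtNum <- function(x) sprintf("%.12g", x)

#' Read / write an expression matrix
#'
#' Expression TSV layout: header row `gene_id<TAB>sample1<TAB>...`, one
#' row per gene, numeric body, genes in rows (GEO series-matrix
#' orientation). Missing values are not permitted: inputs are fully
#' normalized arrays.
#'
#' @param path file path.
#' @return `readExpression`: a [SummarizedExperiment::SummarizedExperiment]
#'   with one assay `expr` (genes x samples).
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(m, tf)
#' se <- readExpression(tf)
#' @export
readExpression <- function(path) {
    rows <- .splitTSV(path)
    if (length(rows) < 2L) stop("expression file has no data rows: ", path)
    header <- rows[[1L]]
    sampleIds <- header[-1L]
    if (anyDuplicated(sampleIds))
        stop("duplicate sample id: ", sampleIds[duplicated(sampleIds)][1L])
    body <- rows[-1L]
    geneIds <- vapply(body, `[`, character(1L), 1L)
    dup <- which(duplicated(geneIds))
    if (length(dup))
        stop("duplicate gene id '", geneIds[dup[1L]], "' at line ",
             dup[1L] + 1L)
    m <- matrix(NA_real_, length(body), length(sampleIds),
                dimnames = list(geneIds, sampleIds))
    for (i in seq_along(body)) {
        vals <- body[[i]][-1L]
        if (length(vals) != length(sampleIds))
            stop("line ", i + 1L, " has ", length(vals),
                 " values but header names ", length(sampleIds), " samples")
        num <- suppressWarnings(as.numeric(vals))
        bad <- which(is.na(num))
        if (length(bad))
            stop("non-numeric value '", vals[bad[1L]], "' at row ", i,
                 " (", geneIds[i], "), column ", sampleIds[bad[1L]])
        m[i, ] <- num
    }
    if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
    .asSE(m)
}

#' @param x a genes x samples matrix or SummarizedExperiment.
#' @rdname readExpression
#' @export
writeExpression <- function(x, path) {
    m <- .exprMatrix(x)
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(paste(c("gene_id", colnames(m)), collapse = "\t"),
                 paste(rownames(m),
                       apply(m, 1L, function(v)
                           paste(.fmtNum(v), collapse = "\t")),
                       sep = "\t")),
               con, sep = "\n")
    invisible(path)
}

#' Read / write a term thesaurus
#'
#' Thesaurus TSV columns: `term_id`, `concept_type`, `canonical`,
#' `synonyms` (pipe-separated surface strings). A surface form shared by
#' two distinct term ids (case-insensitive) is a hard error.
#'
#' @param path file path.
#' @return `readThesaurus`: a [Thesaurus-class] object.
#' @export
readThesaurus <- function(path) {
    rows <- .splitTSV(path)
    if (!length(rows)) stop("empty thesaurus file: ", path)
    header <- rows[[1L]]
    need <- c("term_id", "concept_type", "canonical", "synonyms")
    if (!identical(header[seq_along(need)], need))
        stop("thesaurus header must be: ", paste(need, collapse = ", "))
    body <- rows[-1L]
    terms <- data.frame(
        term_id = vapply(body, `[`, character(1L), 1L),
        concept_type = vapply(body, `[`, character(1L), 2L),
        canonical = vapply(body, `[`, character(1L), 3L),
        stringsAsFactors = FALSE)
    bad <- setdiff(unique(terms$concept_type), CONCEPT_TYPES)
    if (length(bad))
        stop("unknown concept_type '", bad[1L], "'; allowed values: ",
             paste(CONCEPT_TYPES, collapse = ", "))
    synonyms <- lapply(body, function(r) {
        s <- strsplit(r[4L], "|", fixed = TRUE)[[1L]]
        s[nzchar(s)]
    })
    names(synonyms) <- terms$term_id
    thesaurus(terms, synonyms)
}

#' @param x a [Thesaurus-class] object.
#' @rdname readThesaurus
#' @export
writeThesaurus <- function(x, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("term_id\tconcept_type\tcanonical\tsynonyms",
                 paste(x@terms$term_id, x@terms$concept_type,
                       x@terms$canonical,
                       vapply(x@terms$term_id, function(id)
                           paste(x@synonyms[[id]], collapse = "|"),
                           character(1L)),
                       sep = "\t")),
               con, sep = "\n")
    invisible(path)
}

#' Read / write a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' A line with no genes is an error (with its line number).
#'
#' @param path file path.
#' @return `readGmt`: a [GeneSetCollection-class] object.
#' @export
readGmt <- function(path) {
    rows <- .splitTSV(path)
    sets <- list(); desc <- character()
    for (i in seq_along(rows)) {
        r <- rows[[i]]
        if (length(r) < 3L || !any(nzchar(r[-(1:2)])))
            stop("GMT line ", i, " has no genes")
        genes <- r[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(genes))
            stop("GMT line ", i, ": duplicate gene '",
                 genes[duplicated(genes)][1L], "' in set ", r[1L])
        sets[[r[1L]]] <- genes
        desc[r[1L]] <- r[2L]
    }
    geneSetCollection(sets, desc)
}

#' @param x a [GeneSetCollection-class] object.
#' @rdname readGmt
#' @export
writeGmt <- function(x, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(vapply(names(x@sets), function(nm)
        paste(c(nm, x@descriptions[[nm]], x@sets[[nm]]), collapse = "\t"),
        character(1L)), con, sep = "\n")
    invisible(path)
}

#' Read / write a JSONL corpus
#'
#' One JSON object per line with fields `doc_id` and `text`. An empty
#' file is a valid corpus with zero documents.
#'
#' @param path file path.
#' @return `readCorpus`: a [Corpus-class] object.
#' @export
readCorpus <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(corpus())
    docs <- lapply(lines, jsonlite::fromJSON)
    ok <- vapply(docs, function(d) all(c("doc_id", "text") %in% names(d)),
                 logical(1L))
    if (!all(ok))
        stop("corpus line ", which(!ok)[1L], " lacks doc_id/text fields")
    corpus(vapply(docs, function(d) as.character(d$doc_id), character(1L)),
           vapply(docs, function(d) as.character(d$text), character(1L)))
}

#' @param x a [Corpus-class] object.
#' @rdname readCorpus
#' @export
writeCorpus <- function(x, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    if (nDocs(x))
        writeLines(vapply(seq_len(nDocs(x)), function(i)
            jsonlite::toJSON(list(doc_id = x@docIds[i], text = x@texts[i]),
                             auto_unbox = TRUE),
            character(1L)), con, sep = "\n")
    invisible(path)
}

#' Read / write a strain-by-trait table
#'
#' TSV layout: header `sample_id<TAB>trait1<TAB>...`, one row per sample
#' (strain). Missing values are encoded as `NA`.
#'
#' @param path file path.
#' @return `readTraits`: a [TraitTable-class] object.
#' @export
readTraits <- function(path) {
    rows <- .splitTSV(path)
    if (length(rows) < 2L) stop("trait file has no data rows: ", path)
    traits <- rows[[1L]][-1L]
    body <- rows[-1L]
    samples <- vapply(body, `[`, character(1L), 1L)
    if (anyDuplicated(samples))
        stop("duplicate sample id: ", samples[duplicated(samples)][1L])
    m <- matrix(NA_real_, length(samples), length(traits),
                dimnames = list(samples, traits))
    for (i in seq_along(body)) {
        vals <- body[[i]][-1L]
        if (length(vals) != length(traits))
            stop("line ", i + 1L, " has ", length(vals),
                 " values but header names ", length(traits), " traits")
        isNA <- vals == "NA"
        num <- suppressWarnings(as.numeric(vals))
        bad <- which(is.na(num) & !isNA)
        if (length(bad))
            stop("non-numeric value '", vals[bad[1L]], "' at row ", i,
                 " (", samples[i], "), column ", traits[bad[1L]])
        m[i, ] <- num
    }
    traitTable(m)
}

#' @param x a [TraitTable-class] object.
#' @rdname readTraits
#' @export
writeTraits <- function(x, path) {
    v <- x@values
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(paste(c("sample_id", colnames(v)), collapse = "\t"),
                 paste(rownames(v),
                       apply(v, 1L, function(r)
                           paste(ifelse(is.na(r), "NA", .fmtNum(r)),
                                 collapse = "\t")),
                       sep = "\t")),
               con, sep = "\n")
    invisible(path)
}

#' Write / read a co-occurrence network as TSV
#'
#' Two files: `<path>` with columns `term_a`, `term_b`, `weight`, and
#' `<path>.nodes` with columns `term_id`, `concept_type`, `doc_count`.
#'
#' @param x a [CooccurrenceNetwork-class] object.
#' @param path edge-table file path.
#' @export
writeNetwork <- function(x, path) {
    e <- x@edges; n <- x@nodes
    con <- file(path, "wb")
    writeLines(c("term_a\tterm_b\tweight",
                 if (nrow(e)) paste(e$term_a, e$term_b, e$weight, sep = "\t")),
               con, sep = "\n")
    close(con)
    con <- file(paste0(path, ".nodes"), "wb")
    writeLines(c("term_id\tconcept_type\tdoc_count",
                 if (nrow(n)) paste(n$term_id, n$concept_type, n$doc_count,
                                    sep = "\t")),
               con, sep = "\n")
    close(con)
    invisible(path)
}

#' @rdname writeNetwork
#' @return `readNetwork`: a [CooccurrenceNetwork-class] object.
#' @export
readNetwork <- function(path) {
    e <- utils::read.delim(path, colClasses = c("character", "character",
                                                "integer"))
    n <- utils::read.delim(paste0(path, ".nodes"),
                           colClasses = c("character", "character",
                                          "integer"))
    new("CooccurrenceNetwork", nodes = n, edges = e)
}
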