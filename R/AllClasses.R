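## Central S4 data objects. Expression matrices travel as one-assay
## SummarizedExperiment objects (genes x samples); the classes below cover
## the literature, trait and truth containers the pipeline moves between
## stages.

CONCEPT_TYPES <- c("gene", "disease", "phenotype", "chemical", "drug",
                   "go_category")

## ---------------------------------------------------------------------------
## ModuleSpec / SyntheticTruth

#' Planted co-expression module
#'
#' Describes one block of correlated genes planted by the synthetic-data
#' generator: its member genes, the within-module correlation of the
#' latent-factor model, and the literature concepts planted to co-occur
#' with those genes in the synthetic corpus.
#'
#' @slot moduleId single label.
#' @slot geneIds character vector of member gene labels.
#' @slot rho within-module correlation in `[0, 1]`; under the factor model
#'   the expected pairwise Pearson r of two member genes equals `rho`.
#' @slot linkedConcepts term ids of concepts planted to co-occur with the
#'   module's genes.
#' @export
setClass("ModuleSpec",
    representation(moduleId = "character", geneIds = "character",
                   rho = "numeric", linkedConcepts = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@moduleId) != 1L)
            msg <- c(msg, "moduleId must be a single label")
        if (length(object@geneIds) < 1L || anyDuplicated(object@geneIds))
            msg <- c(msg, "geneIds must be a nonempty set of distinct labels")
        if (length(object@rho) != 1L || is.na(object@rho) ||
            object@rho < 0 || object@rho > 1)
            msg <- c(msg, "rho must lie in [0, 1]")
        if (length(msg)) msg else TRUE
    })

#' @param moduleId,geneIds,rho,linkedConcepts see slot documentation.
#' @return A `ModuleSpec` object.
#' @rdname ModuleSpec-class
#' @export
moduleSpec <- function(moduleId, geneIds, rho, linkedConcepts = character()) {
    new("ModuleSpec", moduleId = as.character(moduleId),
        geneIds = as.character(geneIds), rho = as.numeric(rho),
        linkedConcepts = as.character(linkedConcepts))
}

#' Ground truth planted by the synthetic-data generators
#'
#' Records everything the generators planted so recovery can be scored:
#' the co-expression modules, the linear gene-to-trait effects, and which
#' gene-set names truly contain a module.
#'
#' @slot modules list of [ModuleSpec-class] objects with disjoint gene lists.
#' @slot traitEffects data.frame with columns `gene_id`, `trait_id`,
#'   `beta` (trait units per unit expression) and `sigma` (trait noise sd).
#' @slot enrichedSets named character vector: names are gene-set names,
#'   values the `moduleId` each set truly contains.
#' @export
setClass("SyntheticTruth",
    representation(modules = "list", traitEffects = "data.frame",
                   enrichedSets = "character"),
    validity = function(object) {
        msg <- character()
        ok <- vapply(object@modules, function(m) is(m, "ModuleSpec"),
                     logical(1L))
        if (!all(ok)) msg <- c(msg, "modules must all be ModuleSpec objects")
        else {
            g <- unlist(lapply(object@modules, slot, "geneIds"))
            dup <- g[duplicated(g)]
            if (length(dup))
                msg <- c(msg, paste0("gene '", dup[1L],
                                     "' appears in more than one module"))
        }
        need <- c("gene_id", "trait_id", "beta", "sigma")
        if (nrow(object@traitEffects) &&
            !all(need %in% names(object@traitEffects)))
            msg <- c(msg, "traitEffects needs columns gene_id, trait_id, beta, sigma")
        if (length(msg)) msg else TRUE
    })

#' @param modules,traitEffects,enrichedSets see slot documentation.
#' @return A `SyntheticTruth` object.
#' @rdname SyntheticTruth-class
#' @export
syntheticTruth <- function(modules = list(),
                           traitEffects = data.frame(
                               gene_id = character(), trait_id = character(),
                               beta = numeric(), sigma = numeric(),
                               stringsAsFactors = FALSE),
                           enrichedSets = character()) {
    new("SyntheticTruth", modules = modules, traitEffects = traitEffects,
        enrichedSets = enrichedSets)
}

#' @rdname SyntheticTruth-class
#' @param x a `SyntheticTruth` object.
#' @export
truthModules <- function(x) x@modules

#' @rdname SyntheticTruth-class
#' @export
truthEffects <- function(x) x@traitEffects

#' @rdname SyntheticTruth-class
#' @export
truthEnrichedSets <- function(x) x@enrichedSets

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@modules), "planted module(s),",
        nrow(object@traitEffects), "trait effect(s),",
        length(object@enrichedSets), "enriched set(s)\n")
})

## ---------------------------------------------------------------------------
## Thesaurus

#' Term thesaurus with synonyms
#'
#' Dictionary of typed terms (genes, diseases, phenotypes, chemicals,
#' drugs, GO categories), each with a canonical surface string and one or
#' more synonyms. Recognition is case-insensitive at token boundaries, so
#' no two distinct terms may share a surface form (case-insensitive); such
#' ambiguity is rejected at construction because silent mis-attribution
#' would corrupt co-occurrence counts.
#'
#' @slot terms data.frame with columns `term_id`, `concept_type`,
#'   `canonical`.
#' @slot synonyms list of character vectors, named by `term_id`.
#' @slot surfaceMap named character vector mapping the normalized surface
#'   key of every canonical/synonym to its `term_id` (built internally).
#' @export
setClass("Thesaurus",
    representation(terms = "data.frame", synonyms = "list",
                   surfaceMap = "character"),
    validity = function(object) {
        msg <- character()
        t <- object@terms
        if (!all(c("term_id", "concept_type", "canonical") %in% names(t)))
            return("terms needs columns term_id, concept_type, canonical")
        if (anyDuplicated(t$term_id))
            msg <- c(msg, paste0("duplicate term_id: ",
                                 t$term_id[duplicated(t$term_id)][1L]))
        bad <- setdiff(unique(t$concept_type), CONCEPT_TYPES)
        if (length(bad))
            msg <- c(msg, paste0("unknown concept_type '", bad[1L],
                                 "'; allowed: ",
                                 paste(CONCEPT_TYPES, collapse = ", ")))
        if (!setequal(names(object@synonyms), t$term_id))
            msg <- c(msg, "synonyms must be named by the term_ids")
        if (any(vapply(object@synonyms,
                       function(s) length(s) == 0L || any(!nzchar(s)),
                       logical(1L))))
            msg <- c(msg, "every term needs a nonempty synonym list")
        if (length(msg)) msg else TRUE
    })

#' @param terms,synonyms see slot documentation; `surfaceMap` is derived.
#' @return A `Thesaurus` object.
#' @rdname Thesaurus-class
#' @export
thesaurus <- function(terms, synonyms) {
    terms <- as.data.frame(terms, stringsAsFactors = FALSE)
    surfaces <- mapply(function(id, can) unique(c(can, synonyms[[id]])),
                       terms$term_id, terms$canonical, SIMPLIFY = FALSE)
    keys <- lapply(surfaces, .surfaceKey)
    map <- structure(rep(terms$term_id, lengths(keys)), names = unlist(keys))
    dup <- unique(names(map)[duplicated(names(map))])
    for (k in dup) {
        owners <- unique(map[names(map) == k])
        if (length(owners) > 1L)
            stop("ambiguous surface form '", k, "' maps to term_ids ",
                 paste(owners, collapse = ", "))
    }
    map <- map[!duplicated(names(map))]
    new("Thesaurus", terms = terms, synonyms = synonyms, surfaceMap = map)
}

#' @rdname Thesaurus-class
#' @param x a `Thesaurus` object.
#' @export
termIds <- function(x) x@terms$term_id

#' @rdname Thesaurus-class
#' @export
conceptTypes <- function(x)
    structure(x@terms$concept_type, names = x@terms$term_id)

#' @rdname Thesaurus-class
#' @param termId a single term id.
#' @export
termSurfaces <- function(x, termId) {
    i <- match(termId, x@terms$term_id)
    if (is.na(i)) stop("unknown term_id: ", termId)
    unique(c(x@terms$canonical[i], x@synonyms[[termId]]))
}

setMethod("show", "Thesaurus", function(object) {
    tab <- table(object@terms$concept_type)
    cat("Thesaurus:", nrow(object@terms), "terms (",
        paste(paste0(names(tab), "=", tab), collapse = ", "), ")\n")
})

## ---------------------------------------------------------------------------
## Corpus

#' Document corpus
#'
#' A set of abstracts with unique document ids; the substrate of the
#' literature co-occurrence network.
#'
#' @slot docIds unique document labels.
#' @slot texts free-text body of each document.
#' @export
setClass("Corpus",
    representation(docIds = "character", texts = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@docIds) != length(object@texts))
            msg <- c(msg, "docIds and texts lengths differ")
        if (anyDuplicated(object@docIds))
            msg <- c(msg, paste0("duplicate doc_id: ",
                                 object@docIds[duplicated(object@docIds)][1L]))
        if (length(msg)) msg else TRUE
    })

#' @param docIds,texts see slot documentation.
#' @return A `Corpus` object.
#' @rdname Corpus-class
#' @export
corpus <- function(docIds = character(), texts = character()) {
    new("Corpus", docIds = as.character(docIds), texts = as.character(texts))
}

#' @rdname Corpus-class
#' @param x a `Corpus` object.
#' @export
nDocs <- function(x) length(x@docIds)

#' @rdname Corpus-class
#' @export
docIds <- function(x) x@docIds

#' @rdname Corpus-class
#' @export
docTexts <- function(x) structure(x@texts, names = x@docIds)

setMethod("show", "Corpus", function(object) {
    cat("Corpus:", length(object@docIds), "document(s)\n")
})

## ---------------------------------------------------------------------------
## CooccurrenceNetwork

#' Literature co-occurrence network
#'
#' Terms recognized in at least one document become nodes; an edge weight
#' is the number of documents in which both endpoint terms were
#' recognized. Edges are unordered (stored with `term_a < term_b`), never
#' self-loops, and weights are positive integers.
#'
#' @slot nodes data.frame with columns `term_id`, `concept_type`,
#'   `doc_count` (documents in which the term was recognized).
#' @slot edges data.frame with columns `term_a`, `term_b`, `weight`.
#' @export
setClass("CooccurrenceNetwork",
    representation(nodes = "data.frame", edges = "data.frame"),
    validity = function(object) {
        msg <- character()
        if (!all(c("term_id", "concept_type", "doc_count") %in%
                 names(object@nodes)))
            msg <- c(msg, "nodes needs columns term_id, concept_type, doc_count")
        e <- object@edges
        if (!all(c("term_a", "term_b", "weight") %in% names(e)))
            msg <- c(msg, "edges needs columns term_a, term_b, weight")
        else if (nrow(e)) {
            if (any(e$term_a == e$term_b)) msg <- c(msg, "self-loop edge")
            if (any(e$term_a > e$term_b))
                msg <- c(msg, "edges must be stored with term_a < term_b")
            if (any(e$weight < 1L | e$weight != round(e$weight)))
                msg <- c(msg, "weights must be positive integers")
            if (anyDuplicated(paste(e$term_a, e$term_b)))
                msg <- c(msg, "duplicate edge")
        }
        if (length(msg)) msg else TRUE
    })

#' @rdname CooccurrenceNetwork-class
#' @param x a `CooccurrenceNetwork` object.
#' @export
networkNodes <- function(x) x@nodes

#' @rdname CooccurrenceNetwork-class
#' @export
networkEdges <- function(x) x@edges

#' @rdname CooccurrenceNetwork-class
#' @param a,b term ids.
#' @return `edgeWeight`: the co-occurrence count (0 if no edge).
#' @export
edgeWeight <- function(x, a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    i <- match(paste(lo, hi), paste(x@edges$term_a, x@edges$term_b))
    ifelse(is.na(i), 0L, x@edges$weight[i])
}

setMethod("show", "CooccurrenceNetwork", function(object) {
    cat("CooccurrenceNetwork:", nrow(object@nodes), "node(s),",
        nrow(object@edges), "edge(s)\n")
})

## ---------------------------------------------------------------------------
## CorrelationMatrix / NeighborList

#' Gene-gene Pearson correlation matrix
#'
#' Symmetric matrix of sample Pearson coefficients with unit diagonal.
#' Genes with zero variance are assigned r = 0 against all partners and
#' listed in `zeroVariance` so the matrix stays total and downstream KNN
#' extraction stays deterministic.
#'
#' @slot r symmetric numeric matrix, dimnames = gene ids.
#' @slot zeroVariance gene ids flagged as having zero variance.
#' @export
setClass("CorrelationMatrix",
    representation(r = "matrix", zeroVariance = "character"),
    validity = function(object) {
        r <- object@r
        msg <- character()
        if (nrow(r) != ncol(r) || is.null(rownames(r)) ||
            !identical(rownames(r), colnames(r)))
            msg <- c(msg, "r must be square with identical row/column gene ids")
        else {
            if (max(abs(r - t(r))) > 1e-12) msg <- c(msg, "r must be symmetric")
            if (max(abs(diag(r) - 1)) > 1e-12)
                msg <- c(msg, "diagonal must be 1")
            if (any(abs(r) > 1 + 1e-12)) msg <- c(msg, "|r| exceeds 1")
        }
        if (length(msg)) msg else TRUE
    })

#' @rdname CorrelationMatrix-class
#' @param x a `CorrelationMatrix` object.
#' @export
corValues <- function(x) x@r

#' @rdname CorrelationMatrix-class
#' @export
zeroVarianceGenes <- function(x) x@zeroVariance

setMethod("show", "CorrelationMatrix", function(object) {
    cat("CorrelationMatrix:", nrow(object@r), "gene(s)")
    if (length(object@zeroVariance))
        cat(";", length(object@zeroVariance), "zero-variance gene(s)")
    cat("\n")
})

#' Per-gene K-nearest-neighbor lists
#'
#' For each gene, its `K` most positively correlated partner genes (self
#' excluded), ordered by non-increasing r with exact ties broken by
#' ascending gene id.
#'
#' @slot neighbors list named by gene id; each element a data.frame with
#'   columns `neighbor_id`, `r`.
#' @slot k the requested neighbor count.
#' @export
setClass("NeighborList",
    representation(neighbors = "list", k = "integer"),
    validity = function(object) {
        for (g in names(object@neighbors)) {
            nb <- object@neighbors[[g]]
            if (!all(c("neighbor_id", "r") %in% names(nb)))
                return("neighbor entries need columns neighbor_id, r")
            if (g %in% nb$neighbor_id)
                return(paste0("gene '", g, "' lists itself as a neighbor"))
            if (is.unsorted(-nb$r)) return("r must be non-increasing")
        }
        TRUE
    })

#' @rdname NeighborList-class
#' @param x a `NeighborList` object.
#' @param gene a single gene id.
#' @export
neighborsOf <- function(x, gene) {
    nb <- x@neighbors[[gene]]
    if (is.null(nb)) stop("gene '", gene, "' has no neighbor entry")
    nb
}

#' @rdname NeighborList-class
#' @export
neighborGenes <- function(x) names(x@neighbors)

#' @rdname NeighborList-class
#' @export
neighborK <- function(x) x@k

setMethod("show", "NeighborList", function(object) {
    cat("NeighborList: K =", object@k, "for", length(object@neighbors),
        "gene(s)\n")
})

## ---------------------------------------------------------------------------
## GeneSetCollection / TraitTable

#' Gene-set collection (GMT)
#'
#' Named gene sets with free-text descriptions, as carried by GMT files.
#'
#' @slot sets list of unique character vectors of gene ids, named by set.
#' @slot descriptions character vector named by set.
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character"),
    validity = function(object) {
        msg <- character()
        if (anyDuplicated(names(object@sets)))
            msg <- c(msg, "set names must be unique")
        if (any(vapply(object@sets, anyDuplicated, integer(1L)) > 0L))
            msg <- c(msg, "genes within a set must be unique")
        if (any(lengths(object@sets) == 0L))
            msg <- c(msg, "gene sets must be nonempty")
        if (!setequal(names(object@descriptions), names(object@sets)))
            msg <- c(msg, "descriptions must be named by the set names")
        if (length(msg)) msg else TRUE
    })

#' @param sets,descriptions see slot documentation; descriptions default
#'   to empty strings.
#' @return A `GeneSetCollection` object.
#' @rdname GeneSetCollection-class
#' @export
geneSetCollection <- function(sets, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- structure(rep("", length(sets)), names = names(sets))
    new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection` object.
#' @export
geneSets <- function(x) x@sets

#' @rdname GeneSetCollection-class
#' @export
setDescriptions <- function(x) x@descriptions

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "set(s), sizes ",
        if (length(object@sets))
            paste(range(lengths(object@sets)), collapse = "-") else "-", "\n")
})

#' Strain-by-trait phenotype table
#'
#' Real-valued phenotype measurements over a strain panel; missing values
#' are allowed and handled downstream by pairwise deletion.
#'
#' @slot values numeric matrix, samples (strains) x traits, with dimnames.
#' @export
setClass("TraitTable",
    representation(values = "matrix"),
    validity = function(object) {
        v <- object@values
        msg <- character()
        if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
        if (is.null(rownames(v)) || is.null(colnames(v)))
            msg <- c(msg, "values must carry sample and trait names")
        else {
            if (anyDuplicated(rownames(v)))
                msg <- c(msg, "duplicate sample id")
            if (anyDuplicated(colnames(v)))
                msg <- c(msg, "duplicate trait id")
        }
        if (length(msg)) msg else TRUE
    })

#' @param values see slot documentation.
#' @return A `TraitTable` object.
#' @rdname TraitTable-class
#' @export
traitTable <- function(values) new("TraitTable", values = values)

#' @rdname TraitTable-class
#' @param x a `TraitTable` object.
#' @export
traitValues <- function(x) x@values

#' @rdname TraitTable-class
#' @export
traitIds <- function(x) colnames(x@values)

setMethod("show", "TraitTable", function(object) {
    cat("TraitTable:", nrow(object@values), "sample(s) x",
        ncol(object@values), "trait(s);",
        sum(is.na(object@values)), "missing value(s)\n")
})
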