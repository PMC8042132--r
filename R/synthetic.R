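## Synthetic-data generators with planted, recoverable structure:
## block-correlated expression modules (single-factor model), a corpus in
## which module genes co-occur with their planted concepts above
## background, strain trait panels with planted linear gene effects, and
## gene-set collections containing planted modules. All randomness flows
## from one explicit integer seed per generator; the caller's RNG state
## is untouched.

#' Simulate a gene expression matrix with planted co-expression modules
#'
#' Each gene of a module `m` with correlation `rho` is generated as
#' `x_g = sqrt(rho) * f_m + sqrt(1 - rho) * eps_g` per sample, with the
#' module factor `f_m` and the gene noise `eps_g` independent standard
#' normals, so the expected pairwise Pearson r of two module genes is
#' `rho`. Non-module genes are independent standard normal.
#'
#' @param nGenes number of genes; labels are `G0001`, `G0002`, ...
#' @param nSamples number of samples (>= 3); labels `S0001`, ...
#' @param modules list of [ModuleSpec-class] objects with disjoint gene
#'   lists drawn from the gene labels.
#' @param seed integer seed.
#' @return list with `expr` (a SummarizedExperiment, genes x samples)
#'   and `truth` (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateExpression(20, 50,
#'     list(moduleSpec("M1", sprintf("G%04d", 1:5), rho = 0.8)), seed = 1)
#' @export
simulateExpression <- function(nGenes, nSamples, modules = list(),
                               seed = 1L) {
    if (nSamples < 3L) stop("nSamples must be >= 3")
    genes <- sprintf("G%04d", seq_len(nGenes))
    samples <- sprintf("S%04d", seq_len(nSamples))
    modGenes <- unlist(lapply(modules, slot, "geneIds"))
    dup <- modGenes[duplicated(modGenes)]
    if (length(dup))
        stop("gene '", dup[1L], "' appears in more than one module")
    unknown <- setdiff(modGenes, genes)
    if (length(unknown))
        stop("module gene '", unknown[1L], "' is outside the ", nGenes,
             "-gene label set")
    m <- withSeed(seed, {
        x <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples,
                    dimnames = list(genes, samples))
        for (mod in modules) {
            f <- stats::rnorm(nSamples)
            rho <- mod@rho
            x[mod@geneIds, ] <- sqrt(rho) * rep(f, each = length(mod@geneIds)) +
                sqrt(1 - rho) * x[mod@geneIds, , drop = FALSE]
        }
        x
    })
    list(expr = .asSE(m), truth = syntheticTruth(modules = modules))
}

#' Build a synthetic thesaurus over genes and concepts
#'
#' One gene term per gene label (canonical = the label, plus a
#' hyphenated synonym) and one term per concept id with a `-syn`
#' synonym. Surface forms are constructed to be unambiguous.
#'
#' @param geneIds gene labels.
#' @param conceptIds concept term ids.
#' @param conceptType concept type for all concepts (default
#'   `"phenotype"`).
#' @return A [Thesaurus-class] object.
#' @export
simulateThesaurus <- function(geneIds, conceptIds,
                              conceptType = "phenotype") {
    ids <- c(geneIds, conceptIds)
    terms <- data.frame(
        term_id = ids,
        concept_type = c(rep("gene", length(geneIds)),
                         rep(conceptType, length(conceptIds))),
        canonical = ids,
        stringsAsFactors = FALSE)
    synonyms <- c(lapply(geneIds, function(g) paste0(g, "-gene")),
                  lapply(conceptIds, function(cc) paste0(cc, "-syn")))
    names(synonyms) <- ids
    thesaurus(terms, synonyms)
}

## filler vocabulary for document text; collisions with thesaurus
## surfaces are dropped at generation time
.FILLERS <- c("the", "of", "in", "a", "with", "study", "results",
              "analysis", "we", "observed", "expression", "levels",
              "samples", "between", "role")

#' Simulate a document corpus with planted gene-concept co-occurrence
#'
#' A signal document (probability `pSignal`) picks one planted module
#' uniformly and mentions a random subset of its genes together with all
#' of the module's linked concepts; a background document mentions terms
#' drawn uniformly from the whole thesaurus. Each mentioned term
#' contributes exactly one surface form (chosen uniformly among
#' canonical and synonyms); filler tokens are interspersed.
#'
#' @param thes a [Thesaurus-class] covering all module genes and linked
#'   concepts.
#' @param truth a [SyntheticTruth-class] with the planted modules.
#' @param nDocs number of documents.
#' @param pSignal probability a document is a module document.
#' @param mentionsPerDoc number of term mentions per document.
#' @param seed integer seed.
#' @return A [Corpus-class] object.
#' @export
simulateCorpus <- function(thes, truth, nDocs, pSignal = 0.5,
                           mentionsPerDoc = 5L, seed = 1L) {
    mods <- truthModules(truth)
    ids <- termIds(thes)
    planted <- unique(unlist(lapply(mods, slot, "linkedConcepts")))
    missing <- setdiff(planted, ids)
    if (length(missing))
        stop("thesaurus is missing planted concept '", missing[1L], "'")
    missingG <- setdiff(unlist(lapply(mods, slot, "geneIds")), ids)
    if (length(missingG))
        stop("thesaurus is missing module gene '", missingG[1L], "'")
    fillers <- setdiff(.FILLERS, names(thes@surfaceMap))
    withSeed(seed, {
        texts <- vapply(seq_len(nDocs), function(i) {
            isSignal <- length(mods) > 0L &&
                stats::runif(1L) < pSignal
            terms <- if (isSignal) {
                mod <- mods[[sample.int(length(mods), 1L)]]
                ng <- min(mentionsPerDoc, length(mod@geneIds))
                c(sample(mod@geneIds, ng), mod@linkedConcepts)
            } else {
                sample(ids, min(mentionsPerDoc, length(ids)))
            }
            surfaces <- vapply(terms, function(t) {
                s <- termSurfaces(thes, t)
                s[sample.int(length(s), 1L)]
            }, character(1L))
            words <- sample(c(surfaces,
                              sample(fillers, 3L, replace = TRUE)))
            paste(words, collapse = " ")
        }, character(1L))
        corpus(sprintf("D%05d", seq_len(nDocs)), texts)
    })
}

#' Simulate strain phenotypes with planted linear gene effects
#'
#' Each trait is `sum_g beta_g * x_g + N(0, sigma^2)` across the panel's
#' samples (strains), using the effects table of the truth object.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param effects data.frame with columns `gene_id`, `trait_id`, `beta`,
#'   `sigma` (one sigma per trait; the first row's value is used).
#' @param seed integer seed.
#' @return A [TraitTable-class] (samples x traits).
#' @export
simulateTraits <- function(expr, effects, seed = 1L) {
    m <- .exprMatrix(expr)
    unknown <- setdiff(effects$gene_id, rownames(m))
    if (length(unknown))
        stop("trait effect references unknown gene '", unknown[1L], "'")
    traits <- unique(effects$trait_id)
    withSeed(seed, {
        v <- vapply(traits, function(tr) {
            ef <- effects[effects$trait_id == tr, , drop = FALSE]
            mu <- colSums(m[ef$gene_id, , drop = FALSE] * ef$beta)
            mu + stats::rnorm(ncol(m), 0, ef$sigma[1L])
        }, numeric(ncol(m)))
        v <- matrix(v, ncol = length(traits),
                    dimnames = list(colnames(m), traits))
        traitTable(v)
    })
}

#' Build gene sets containing planted modules plus decoys
#'
#' One set per entry of the truth's `enrichedSets` map, holding the named
#' module's genes padded with random universe genes to `setSize`; decoy
#' sets are drawn uniformly from the universe.
#'
#' @param truth a [SyntheticTruth-class] whose `enrichedSets` names the
#'   planted sets (values are module ids).
#' @param nDecoySets number of decoy sets (named `DECOY_...`).
#' @param setSize genes per set (must not exceed the universe size).
#' @param universe gene labels to draw from.
#' @param seed integer seed.
#' @return A [GeneSetCollection-class] object.
#' @export
makeGeneSets <- function(truth, nDecoySets, setSize, universe, seed = 1L) {
    if (setSize > length(universe))
        stop("setSize exceeds the universe size")
    mods <- truthModules(truth)
    modIdx <- vapply(mods, slot, character(1L), "moduleId")
    withSeed(seed, {
        sets <- list()
        es <- truthEnrichedSets(truth)
        for (nm in names(es)) {
            mod <- mods[[match(es[[nm]], modIdx)]]
            g <- intersect(mod@geneIds, universe)
            pad <- sample(setdiff(universe, g), setSize - length(g))
            sets[[nm]] <- c(g, pad)
        }
        for (i in seq_len(nDecoySets))
            sets[[sprintf("DECOY_%03d", i)]] <- sample(universe, setSize)
        geneSetCollection(sets)
    })
}

#' Generate the default synthetic study
#'
#' One call producing every input of the pipeline under the package's
#' default study conditions: a 60-gene, 100-sample expression compendium
#' carrying two 10-gene modules at rho = 0.8, each linked to one planted
#' concept; a thesaurus of the 60 genes, the 2 planted concepts and 88
#' background concepts; a 500-document corpus at pSignal = 0.2 with 4
#' mentions per document (background gene-concept co-occurrence stays
#' sparse, as in real abstract corpora); an independent 38-strain panel
#' over the same genes with one planted trait effect (population
#' r = 0.7 on gene G0001) and one pure-noise trait; and a gene-set
#' collection with one planted set per module (size 20, padded into a
#' 500-gene universe) plus 20 decoys.
#'
#' @param seed integer seed; stage seeds are derived deterministically
#'   from it.
#' @return list with elements `expr`, `truth`, `thesaurus`, `corpus`,
#'   `strainExpr`, `traits`, `geneSets`, `geneUniverse` (the 60
#'   compendium genes), `setUniverse` (the 500-gene ORA background).
#' @export
simulateStudy <- function(seed = 1L) {
    seed <- as.integer(seed)
    genes <- sprintf("G%04d", 1:60)
    mods <- list(moduleSpec("M1", genes[1:10], rho = 0.8,
                            linkedConcepts = "C01"),
                 moduleSpec("M2", genes[11:20], rho = 0.8,
                            linkedConcepts = "C02"))
    sim <- simulateExpression(60, 100, mods, seed = seed)
    truth <- syntheticTruth(
        modules = mods,
        traitEffects = data.frame(
            gene_id = c("G0001", "G0021"),
            trait_id = c("T_planted", "T_null"),
            beta = c(0.7, 0),
            sigma = c(sqrt(1 - 0.7^2), 1),
            stringsAsFactors = FALSE),
        enrichedSets = c(SET_M1 = "M1", SET_M2 = "M2"))
    thes <- simulateThesaurus(genes, sprintf("C%02d", 1:90))
    corp <- simulateCorpus(thes, truth, nDocs = 500, pSignal = 0.2,
                           mentionsPerDoc = 4L, seed = seed + 101L)
    strain <- simulateExpression(60, 38, mods, seed = seed + 202L)
    traits <- simulateTraits(strain$expr, truthEffects(truth),
                             seed = seed + 303L)
    setUniverse <- c(genes, sprintf("U%04d", 61:500))
    gs <- makeGeneSets(truth, nDecoySets = 20L, setSize = 20L,
                       universe = setUniverse, seed = seed + 404L)
    list(expr = sim$expr, truth = truth, thesaurus = thes, corpus = corp,
         strainExpr = strain$expr, traits = traits, geneSets = gs,
         geneUniverse = genes, setUniverse = setUniverse)
}
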