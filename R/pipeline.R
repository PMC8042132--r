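## Pipeline driver: wires the stages (simulate -> coexpress -> litnet ->
## gamma -> assoc -> enrich -> profile) through documented on-disk
## formats only, so any stage can be rerun or inspected in isolation,
## and writes a deterministic run manifest (parameters, seeds, file
## checksums).

.STAGES <- c("simulate", "coexpress", "litnet", "gamma", "assoc",
             "enrich", "profile")

#' Default pipeline configuration
#'
#' Stage parameters default to the procedure's standard values where one
#' exists: K = 40 co-expression neighbors, minimum 2 shared relations,
#' ORA minimum overlap 5, screening alpha 0.05, adjusted-p threshold
#' 0.05. `zCutoff = 3.5` is the usual robust-outlier convention for the
#' modified Z-score.
#'
#' @param outDir output directory.
#' @param seed global seed; per-stage seeds are derived from it by a
#'   fixed schedule inside the generators.
#' @return A named list understood by [runPipeline()].
#' @export
defaultConfig <- function(outDir = "gba-run", seed = 1L) {
    list(seed = as.integer(seed), outDir = outDir, stages = .STAGES,
         k = 40L, minShared = 2L, wMin = 1L, conceptTypes = NULL,
         keywords = NULL, alpha = 0.05, minOverlap = 5L,
         alphaAdj = 0.05, top = 10L, zCutoff = 3.5,
         enrichGene = NULL, inputs = list())
}

.validateConfig <- function(cfg) {
    base <- defaultConfig()
    unknown <- setdiff(names(cfg), names(base))
    if (length(unknown)) stop("unknown config field: ", unknown[1L])
    cfg <- utils::modifyList(base, cfg)
    bad <- setdiff(cfg$stages, .STAGES)
    if (length(bad)) stop("unknown stage: ", bad[1L])
    if (cfg$k < 1L) stop("k must be >= 1")
    if (cfg$minShared < 1L) stop("minShared must be >= 1")
    if (cfg$minOverlap < 1L) stop("minOverlap must be >= 1")
    for (f in c("alpha", "alphaAdj"))
        if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
            stop(f, " must lie in (0, 1)")
    cfg
}

.stageTry <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the guilt-by-association pipeline
#'
#' Executes the requested stages in dependency order, communicating only
#' through files under `outDir`, and writes `manifest.json` recording
#' the parameters, seeds, package version and MD5 checksum of every
#' output, sufficient to reproduce the run byte-identically. Any stage
#' error aborts with the stage name in the message. When the `simulate`
#' stage is requested, all inputs come from [simulateStudy()]; otherwise
#' they are read from the paths in `config$inputs` (fields `expr`,
#' `strainExpr`, `thesaurus`, `corpus`, `traits`, `gmt`, `universe`,
#' `setUniverse`).
#'
#' @param config a list as from [defaultConfig()] (missing fields take
#'   their defaults) or the path of a YAML file holding one.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config = defaultConfig()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- .validateConfig(config)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character()
    addOut <- function(p) outputs <<- c(outputs, p)
    st <- cfg$stages

    expr <- strainExpr <- thes <- corp <- traits <- gs <- NULL
    geneUniverse <- setUniverse <- NULL
    if ("simulate" %in% st) {
        study <- .stageTry("simulate", simulateStudy(cfg$seed))
        expr <- study$expr; strainExpr <- study$strainExpr
        thes <- study$thesaurus; corp <- study$corpus
        traits <- study$traits; gs <- study$geneSets
        geneUniverse <- study$geneUniverse
        setUniverse <- study$setUniverse
        ind <- file.path(cfg$outDir, "inputs")
        dir.create(ind, showWarnings = FALSE)
        .stageTry("simulate", {
            addOut(writeExpression(expr, file.path(ind, "expr.tsv")))
            addOut(writeExpression(strainExpr,
                                   file.path(ind, "strain_expr.tsv")))
            addOut(writeThesaurus(thes, file.path(ind, "thesaurus.tsv")))
            addOut(writeCorpus(corp, file.path(ind, "corpus.jsonl")))
            addOut(writeTraits(traits, file.path(ind, "traits.tsv")))
            addOut(writeGmt(gs, file.path(ind, "sets.gmt")))
            writeLines(geneUniverse, file.path(ind, "universe.txt"))
            addOut(file.path(ind, "universe.txt"))
            tr <- study$truth
            jsonlite::write_json(list(
                modules = lapply(truthModules(tr), function(m)
                    list(module_id = m@moduleId, gene_ids = m@geneIds,
                         rho = m@rho, linked_concepts = m@linkedConcepts)),
                trait_effects = truthEffects(tr),
                enriched_sets = as.list(truthEnrichedSets(tr))),
                file.path(ind, "truth.json"), auto_unbox = TRUE,
                digits = NA)
            addOut(file.path(ind, "truth.json"))
        })
    } else {
        inp <- cfg$inputs
        need <- function(f) {
            if (is.null(inp[[f]])) stop("config$inputs$", f,
                                        " is required without the ",
                                        "simulate stage")
            inp[[f]]
        }
        if (length(intersect(st, c("coexpress", "gamma", "enrich"))))
            expr <- readExpression(need("expr"))
        if (length(intersect(st, c("assoc", "profile"))))
            strainExpr <- readExpression(
                if (is.null(inp$strainExpr)) need("expr") else
                    inp$strainExpr)
        if ("litnet" %in% st) {
            thes <- readThesaurus(need("thesaurus"))
            corp <- readCorpus(need("corpus"))
        }
        if ("assoc" %in% st) traits <- readTraits(need("traits"))
        if ("enrich" %in% st) gs <- readGmt(need("gmt"))
        if (length(intersect(st, c("gamma", "enrich")))) {
            geneUniverse <- readLines(need("universe"))
            setUniverse <- if (is.null(inp$setUniverse)) geneUniverse
                           else readLines(inp$setUniverse)
        }
    }

    neighbors <- NULL
    if ("coexpress" %in% st) {
        neighbors <- .stageTry("coexpress", {
            norm <- quantileNormalize(expr)
            knnNeighbors(correlationMatrix(norm), k = cfg$k)
        })
        addOut(writeNeighbors(neighbors,
                              file.path(cfg$outDir, "neighbors.tsv")))
    }
    net <- NULL
    if ("litnet" %in% st) {
        net <- .stageTry("litnet", buildNetwork(corp, thes))
        writeNetwork(net, file.path(cfg$outDir, "network.tsv"))
        addOut(file.path(cfg$outDir, "network.tsv"))
        addOut(file.path(cfg$outDir, "network.tsv.nodes"))
    }
    if ("gamma" %in% st) {
        profiles <- .stageTry("gamma", {
            if (is.null(neighbors) || is.null(net))
                stop("requires the coexpress and litnet stages")
            gs2 <- intersect(neighborGenes(neighbors), geneUniverse)
            stats::setNames(lapply(gs2, function(g)
                gammaProfile(g, neighbors, net, geneUniverse,
                             minShared = cfg$minShared, wMin = cfg$wMin,
                             conceptTypes = cfg$conceptTypes,
                             keywords = cfg$keywords)), gs2)
        })
        addOut(writeCommonalities(profiles,
                                  file.path(cfg$outDir,
                                            "commonalities.tsv")))
    }
    if ("assoc" %in% st) {
        res <- .stageTry("assoc",
                         screenAssociations(strainExpr, traits,
                                            alpha = cfg$alpha))
        addOut(writeAssociations(res, file.path(cfg$outDir, "assoc.tsv")))
    }
    if ("enrich" %in% st) {
        res <- .stageTry("enrich", {
            g0 <- cfg$enrichGene
            if (is.null(g0)) g0 <- geneUniverse[1L]
            query <- if (!is.null(neighbors))
                unique(c(g0, neighborsOf(neighbors, g0)$neighbor_id))
            else geneUniverse
            ora(query, gs, setUniverse, minOverlap = cfg$minOverlap,
                alphaAdj = cfg$alphaAdj, top = cfg$top)
        })
        addOut(writeEnrichment(res, file.path(cfg$outDir, "enrich.tsv")))
    }
    if ("profile" %in% st) {
        res <- .stageTry("profile", {
            x <- if (is.null(strainExpr)) expr else strainExpr
            profileExpression(x, cutoff = cfg$zCutoff)
        })
        con <- file(file.path(cfg$outDir, "profile.tsv"), "wb")
        writeLines(c("gene_id\tmean_expr\tmodified_z\thigh",
                     paste(res$gene_id, .fmtNum(res$mean_expr),
                           .fmtNum(res$modified_z), tolower(res$high),
                           sep = "\t")), con, sep = "\n")
        close(con)
        addOut(file.path(cfg$outDir, "profile.tsv"))
    }

    manifest <- list(
        package = "gbanet",
        version = as.character(utils::packageVersion("gbanet")),
        parameters = cfg[setdiff(names(cfg), c("outDir", "inputs"))],
        skipped_stages = setdiff(.STAGES, st),
        outputs = as.list(structure(
            unname(tools::md5sum(outputs)),
            names = sub(paste0("^", cfg$outDir, "/?"), "", outputs))))
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(manifest)
}
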