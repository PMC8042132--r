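test_that("factor model produces the planted correlation structure", {
    ## rho = 1: both genes are the module factor itself
    sim <- simulateExpression(2, 10,
        list(moduleSpec("M", c("G0001", "G0002"), rho = 1)), seed = 3)
    m <- SummarizedExperiment::assay(sim$expr)
    expect_equal(cor(m["G0001", ], m["G0002", ]), 1)

    ## rho = 0: no structure anywhere
    sim0 <- simulateExpression(50, 500, list(), seed = 5)
    r <- cor(t(SummarizedExperiment::assay(sim0$expr)))
    expect_lt(mean(abs(r[upper.tri(r)])), 0.1)

    ## rho = 0.8, module of 10, n = 200: Monte-Carlo mean pairwise r
    ## equals rho under the factor model (E[r] = rho)
    mod <- list(moduleSpec("M", sprintf("G%04d", 1:10), rho = 0.8))
    rs <- vapply(1:200, function(s) {
        m <- SummarizedExperiment::assay(
            simulateExpression(10, 200, mod, seed = s)$expr)
        r <- cor(t(m))
        mean(r[upper.tri(r)])
    }, numeric(1))
    expect_gte(mean(rs), 0.75)
    expect_lte(mean(rs), 0.85)
})

test_that("expression generator rejects overlapping modules and bad labels", {
    mods <- list(moduleSpec("M1", c("G0001", "G0002"), 0.5),
                 moduleSpec("M2", c("G0002", "G0003"), 0.5))
    expect_error(simulateExpression(10, 10, mods, seed = 1), "G0002")
    expect_error(
        simulateExpression(2, 10, list(moduleSpec("M", "G0099", 0.5))),
        "G0099")
    expect_error(simulateExpression(5, 2, list(), seed = 1), "nSamples")
})

test_that("generators are reproducible per seed and leave the RNG alone", {
    a <- simulateExpression(20, 30, list(), seed = 42)
    b <- simulateExpression(20, 30, list(), seed = 42)
    expect_identical(SummarizedExperiment::assay(a$expr),
                     SummarizedExperiment::assay(b$expr))
    set.seed(99); before <- rnorm(1)
    set.seed(99); invisible(simulateExpression(5, 5, list(), seed = 1))
    expect_identical(rnorm(1), before)

    s1 <- simulateStudy(11); s2 <- simulateStudy(11)
    expect_identical(docTexts(s1$corpus), docTexts(s2$corpus))
    expect_identical(traitValues(s1$traits), traitValues(s2$traits))
    expect_identical(geneSets(s1$geneSets), geneSets(s2$geneSets))
})

test_that("signal documents always carry the planted concept", {
    genes <- sprintf("G%04d", 1:5)
    mod <- moduleSpec("M", genes, rho = 0.8, linkedConcepts = "C01")
    truth <- syntheticTruth(modules = list(mod))
    thes <- simulateThesaurus(genes, c("C01", "C02"))
    corp <- simulateCorpus(thes, truth, nDocs = 100, pSignal = 1,
                           mentionsPerDoc = 3, seed = 8)
    for (txt in docTexts(corp)) {
        terms <- recognizeTerms(txt, thes)
        if (any(terms %in% genes)) expect_true("C01" %in% terms)
    }
})

test_that("planted concepts co-occur with their module's genes above the other module's", {
    genes <- sprintf("G%04d", 1:20)
    mods <- list(moduleSpec("M1", genes[1:10], 0.8, "C01"),
                 moduleSpec("M2", genes[11:20], 0.8, "C02"))
    truth <- syntheticTruth(modules = mods)
    thes <- simulateThesaurus(genes, c("C01", "C02"))
    corp <- simulateCorpus(thes, truth, nDocs = 2000, pSignal = 0.5,
                           mentionsPerDoc = 5, seed = 13)
    net <- buildNetwork(corp, thes)
    ok <- c(vapply(genes[1:10], function(g)
                edgeWeight(net, g, "C01") > edgeWeight(net, g, "C02"),
                logical(1)),
            vapply(genes[11:20], function(g)
                edgeWeight(net, g, "C02") > edgeWeight(net, g, "C01"),
                logical(1)))
    expect_gte(mean(ok), 0.95)
})

test_that("corpus generator validates the thesaurus", {
    mod <- moduleSpec("M", "G0001", 0.5, linkedConcepts = "MISSING")
    truth <- syntheticTruth(modules = list(mod))
    thes <- simulateThesaurus("G0001", "C01")
    expect_error(simulateCorpus(thes, truth, 10, seed = 1), "MISSING")
})

test_that("trait simulation follows the linear model", {
    sim <- simulateExpression(5, 20, list(), seed = 2)
    m <- SummarizedExperiment::assay(sim$expr)
    ## sigma = 0, beta = 1: the trait is the gene's expression row
    eff <- data.frame(gene_id = "G0002", trait_id = "T1", beta = 1,
                      sigma = 0)
    tt <- simulateTraits(sim$expr, eff, seed = 4)
    expect_equal(unname(traitValues(tt)[, "T1"]), unname(m["G0002", ]))
    expect_equal(cor(traitValues(tt)[, "T1"], m["G0002", ]), 1)

    expect_error(
        simulateTraits(sim$expr,
                       data.frame(gene_id = "NOPE", trait_id = "T",
                                  beta = 1, sigma = 1), seed = 1),
        "NOPE")
})

test_that("planted gene sets contain their module and respect sizes", {
    genes <- sprintf("G%04d", 1:10)
    truth <- syntheticTruth(
        modules = list(moduleSpec("M1", genes, 0.8)),
        enrichedSets = c(PLANTED = "M1"))
    universe <- sprintf("G%04d", 1:200)
    gs <- makeGeneSets(truth, nDecoySets = 0, setSize = 20,
                       universe = universe, seed = 6)
    expect_length(geneSets(gs), 1L)
    expect_length(intersect(geneSets(gs)$PLANTED, genes), 10L)
    expect_length(geneSets(gs)$PLANTED, 20L)
    expect_error(makeGeneSets(truth, 0, 300, universe, seed = 1),
                 "universe")
})

test_that("generated artifacts satisfy downstream preconditions end to end", {
    study <- simulateStudy(21)
    expect_s4_class(study$thesaurus, "Thesaurus")
    expect_s4_class(study$corpus, "Corpus")
    expect_s4_class(study$traits, "TraitTable")
    ## round-trip through every consuming stage without error
    expect_no_error({
        nb <- knnNeighbors(
            correlationMatrix(quantileNormalize(study$expr)), k = 10)
        net <- buildNetwork(study$corpus, study$thesaurus)
        gammaProfile("G0001", nb, net, study$geneUniverse)
        screenAssociations(study$strainExpr, study$traits)
        ora(truthModules(study$truth)[[1]]@geneIds, study$geneSets,
            study$setUniverse, minOverlap = 5)
        profileExpression(study$strainExpr)
    })
})
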