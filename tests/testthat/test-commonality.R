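## Small networks are built directly from per-document term sets so the
## expected counts can be verified by hand or by enumeration.

test_that("concept gene-degrees count only universe genes", {
    th <- mkThesaurus(c("A", "B", "C", "X"), c("C1", "C2"))
    net <- netFromDocs(list(c("A", "C1"), c("B", "C1"), c("X", "C1"),
                            c("A", "C2"), c("A", "B")), th)
    deg <- conceptDegrees(net, universe = c("A", "B", "C"))
    expect_identical(attr(deg, "N"), 3L)
    expect_identical(deg$d[deg$concept == "C1"], 2L)  # X outside universe
    expect_identical(deg$d[deg$concept == "C2"], 1L)  # gene-gene edges ignored
    expect_error(conceptDegrees(net, character()), "nonempty")
})

test_that("a concept with no gene edges appears with degree zero and is never scored", {
    th <- mkThesaurus(c("A", "B"), c("C1", "C2"))
    net <- netFromDocs(list(c("A", "C1"), c("B", "C1"), "C2"), th)
    deg <- conceptDegrees(net, c("A", "B"))
    expect_identical(deg$d[deg$concept == "C2"], 0L)
    res <- scoreCommonalities(c("A", "B"), net, c("A", "B"))
    expect_false("C2" %in% res$concept)
})

test_that("the Obs/Exp arithmetic follows the degree-proportional null", {
    ## |query| = 40, d = 10, N = 100, shared = 8 -> expected 4, obs_exp 2,
    ## score 16. Build it explicitly: 100 genes, concept linked to 10,
    ## 8 of which sit in the 40-gene query.
    genes <- sprintf("G%04d", 1:100)
    th <- mkThesaurus(genes, "C1")
    linked <- c(genes[1:8], genes[91:92])        # d = 10
    query <- genes[1:40]                          # shares 8 of them
    net <- netFromDocs(lapply(linked, c, "C1"), th)
    res <- scoreCommonalities(query, net, genes)
    expect_identical(res$shared_rels, 8L)
    expect_equal(res$expected, 4)
    expect_equal(res$obs_exp, 2)
    expect_equal(res$score, 16)
})

test_that("a universally connected concept scores only by coverage", {
    genes <- sprintf("G%02d", 1:12)
    th <- mkThesaurus(genes, "C1")
    net <- netFromDocs(lapply(genes, c, "C1"), th)
    query <- genes[1:5]
    res <- scoreCommonalities(query, net, genes)
    expect_equal(res$obs_exp, 1)
    expect_equal(res$score, length(query))
})

test_that("minShared filtering and query validation apply", {
    th <- mkThesaurus(c("A", "B", "C"), c("C1", "C2"))
    net <- netFromDocs(list(c("A", "C1"), c("B", "C1"), c("A", "C2")), th)
    res <- scoreCommonalities(c("A", "B"), net, c("A", "B", "C"))
    expect_identical(res$concept, "C1")  # C2 shared_rels = 1 < 2
    res1 <- scoreCommonalities(c("A", "B"), net, c("A", "B", "C"),
                               minShared = 1)
    expect_setequal(res1$concept, c("C1", "C2"))
    expect_error(scoreCommonalities(c("A", "Z"), net, c("A", "B")), "Z")
})

test_that("score is exactly shared_rels x obs_exp and monotone in shared_rels", {
    study <- simulateStudy(41)
    net <- buildNetwork(study$corpus, study$thesaurus)
    res <- scoreCommonalities(study$geneUniverse[1:10], net,
                              study$geneUniverse)
    expect_true(nrow(res) > 0)
    expect_identical(res$score, res$shared_rels * res$obs_exp)
    expect_identical(res$obs_exp, res$shared_rels / res$expected)

    ## fixed d, N, |query|: score strictly increases with shared_rels
    sh <- 1:10; d <- 10; N <- 100; q <- 10
    sc <- sh * (sh / (q * d / N))
    expect_true(all(diff(sc) > 0))
})

test_that("expected matches exhaustive enumeration of query subsets", {
    ## On a small network the hypergeometric mean |q| * d / N must equal
    ## the exact average of shared_rels over all C(N, q) query sets.
    genes <- sprintf("G%02d", 1:9)
    th <- mkThesaurus(genes, c("C1", "C2", "C3"))
    set.seed(6)
    docTerms <- c(lapply(sample(genes, 5), c, "C1"),
                  lapply(sample(genes, 3), c, "C2"),
                  lapply(sample(genes, 7), c, "C3"))
    net <- netFromDocs(docTerms, th)
    e <- networkEdges(net)
    q <- 4
    combos <- combn(genes, q)
    for (cc in c("C1", "C2", "C3")) {
        linked <- union(e$term_b[e$term_a == cc], e$term_a[e$term_b == cc])
        sharedAll <- apply(combos, 2, function(qs)
            length(intersect(qs, linked)))
        enumMean <- mean(sharedAll)
        res <- scoreCommonalities(combos[, 1], net, genes, minShared = 0)
        if (cc %in% res$concept)
            expect_equal(res$expected[res$concept == cc], enumMean)
    }
})

test_that("gammaProfile queries the neighbor set without the gene itself", {
    study <- simulateStudy(51)
    nb <- knnNeighbors(
        correlationMatrix(quantileNormalize(study$expr)), k = 10)
    net <- buildNetwork(study$corpus, study$thesaurus)
    p1 <- gammaProfile("G0001", nb, net, study$geneUniverse)
    direct <- scoreCommonalities(
        setdiff(neighborsOf(nb, "G0001")$neighbor_id, "G0001"),
        net, study$geneUniverse)
    expect_identical(p1, direct)
    expect_error(gammaProfile("NOPE", nb, net, study$geneUniverse),
                 "NOPE")

    ## two genes given the same neighbor set yield identical profiles
    nbSame <- new("NeighborList",
                  neighbors = list(X = neighborsOf(nb, "G0001"),
                                   Y = neighborsOf(nb, "G0001")),
                  k = 10L)
    expect_identical(
        gammaProfile("X", nbSame, net, study$geneUniverse),
        gammaProfile("Y", nbSame, net, study$geneUniverse))
})

test_that("genes whose neighbors lack literature edges give an empty profile", {
    th <- mkThesaurus(c("A", "B", "C"), "C1")
    net <- netFromDocs(list(c("A", "B")), th)  # no concept edges at all
    nb <- new("NeighborList",
              neighbors = list(A = data.frame(neighbor_id = c("B", "C"),
                                              r = c(0.9, 0.5))),
              k = 2L)
    res <- gammaProfile("A", nb, net, c("A", "B", "C"))
    expect_identical(nrow(res), 0L)
})

test_that("null corpora produce obs_exp consistent with redrawn query sets", {
    ## p_signal = 0: no concept is attached to any module; the observed
    ## 95th percentile of obs_exp (shared >= 2) for a random query must
    ## sit inside the distribution obtained by redrawing query sets.
    genes <- sprintf("G%04d", 1:30)
    truth <- syntheticTruth()
    th <- simulateThesaurus(genes, sprintf("C%02d", 1:20))
    corp <- simulateCorpus(th, truth, nDocs = 400, pSignal = 0,
                           mentionsPerDoc = 4, seed = 61)
    net <- buildNetwork(corp, th)
    p95 <- function(qs) {
        r <- scoreCommonalities(qs, net, genes)
        if (nrow(r)) quantile(r$obs_exp, 0.95) else 0
    }
    set.seed(62)
    obs <- p95(sample(genes, 8))
    redraws <- replicate(200, p95(sample(genes, 8)))
    expect_lte(obs, max(redraws))
    expect_lte(obs, quantile(redraws, 0.995) + 1e-9)
})
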