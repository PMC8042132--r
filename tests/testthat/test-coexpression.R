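test_that("quantile normalization maps samples onto the rank-mean reference", {
    m <- mkExpr(c(5, 1, 3, 2, 4, 6), 3, 2)
    out <- quantileNormalize(m)
    expect_equal(unname(out[, 1]), c(5.5, 1.5, 3.5))
    expect_equal(unname(out[, 2]), c(1.5, 3.5, 5.5))

    ## two identical samples: normalization is a fixed point
    m2 <- mkExpr(c(2, 7, 4, 2, 7, 4), 3, 2)
    expect_equal(quantileNormalize(m2), m2)

    ## tied entries receive the mean of the reference values at the
    ## tied ranks: ref = (sort(1,1,4) + sort(2,6,10)) / 2 = (1.5,3.5,7)
    m3 <- mkExpr(c(1, 1, 4, 2, 6, 10), 3, 2)
    out3 <- quantileNormalize(m3)
    expect_equal(unname(out3[, 1]), c(2.5, 2.5, 7))
    expect_equal(unname(out3[, 2]), c(1.5, 3.5, 7))

    expect_error(quantileNormalize(mkExpr(1:3, 3, 1)), "2 samples")
})

test_that("quantile normalization agrees with limma on tie-free data", {
    skip_if_not_installed("limma")
    set.seed(1)
    m <- mkExpr(rnorm(200), 20, 10)
    expect_equal(unname(quantileNormalize(m)),
                 unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("quantile normalization preserves within-sample rank order", {
    set.seed(2)
    m <- mkExpr(rnorm(300), 30, 10)
    out <- quantileNormalize(m)
    for (j in seq_len(ncol(m)))
        expect_identical(order(out[, j]), order(m[, j]))
})

test_that("normalization absorbs monotone distortion of a sample", {
    ## A monotone transform of one input sample leaves every sample's
    ## normalized rank pattern unchanged, so rank correlations between
    ## genes are exactly invariant (the pooled reference shifts, so
    ## Pearson values move only slightly).
    set.seed(3)
    m <- mkExpr(rnorm(150), 15, 10)
    distorted <- m
    distorted[, 4] <- exp(m[, 4])  # monotone transform of one sample
    q1 <- quantileNormalize(m)
    q2 <- quantileNormalize(distorted)
    for (j in seq_len(ncol(m)))
        expect_identical(order(q2[, j]), order(q1[, j]))
    expect_equal(cor(t(q1), method = "spearman"),
                 cor(t(q2), method = "spearman"), tolerance = 1e-12)
    expect_equal(corValues(correlationMatrix(q1)),
                 corValues(correlationMatrix(q2)), tolerance = 0.1)
})

test_that("correlation matrix follows the Pearson definition", {
    m <- mkExpr(c(1, 2, 1, 2, 4, 3, 3, 6, 2), 3, 3)  # g2 = 2*g1 + affine
    m["g02", ] <- 2 * m["g01", ] + 1
    m["g03", ] <- -m["g01", ]
    cm <- correlationMatrix(m)
    r <- corValues(cm)
    expect_equal(r["g01", "g02"], 1)
    expect_equal(r["g01", "g03"], -1)

    m2 <- mkExpr(c(1, 1, 2, 3, 3, 2), 2, 3)  # rows (1,2,3), (1,3,2)
    expect_equal(corValues(correlationMatrix(m2))["g01", "g02"], 0.5)

    expect_error(correlationMatrix(mkExpr(1:4, 2, 2)), "3 samples")
})

test_that("zero-variance genes get r = 0 and are flagged", {
    m <- mkExpr(c(1, 5, 1, 3, 1, 4, 1, 9), 2, 4)
    cm <- correlationMatrix(m)
    expect_identical(zeroVarianceGenes(cm), "g01")
    expect_equal(unname(corValues(cm)["g01", "g02"]), 0)
    expect_equal(unname(diag(corValues(cm))), c(1, 1))
})

test_that("KNN extraction ranks, truncates and breaks ties as declared", {
    r <- diag(3)
    dimnames(r) <- list(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
    r["g1", "g2"] <- r["g2", "g1"] <- 0.9
    r["g1", "g3"] <- r["g3", "g1"] <- 0.1
    r["g2", "g3"] <- r["g3", "g2"] <- 0.2
    cm <- new("CorrelationMatrix", r = r, zeroVariance = character())
    nb <- knnNeighbors(cm, k = 1)
    expect_identical(neighborsOf(nb, "g1")$neighbor_id, "g2")
    expect_identical(neighborsOf(nb, "g2")$neighbor_id, "g1")
    expect_identical(neighborsOf(nb, "g3")$neighbor_id, "g2")

    ## K larger than n - 1 truncates
    nb5 <- knnNeighbors(cm, k = 5)
    expect_true(all(vapply(neighborGenes(nb5), function(g)
        nrow(neighborsOf(nb5, g)) == 2L, logical(1))))

    ## exact tie broken by ascending gene id
    rt <- diag(3)
    dimnames(rt) <- list(c("Q", "A", "B"), c("Q", "A", "B"))
    rt["Q", "A"] <- rt["A", "Q"] <- 0.5
    rt["Q", "B"] <- rt["B", "Q"] <- 0.5
    cmt <- new("CorrelationMatrix", r = rt, zeroVariance = character())
    expect_identical(
        neighborsOf(knnNeighbors(cmt, k = 1), "Q")$neighbor_id, "A")

    expect_error(knnNeighbors(cm, k = 0), "k must be")
})

test_that("KNN matches a brute-force row sort on small matrices", {
    for (s in 1:5) {
        set.seed(s)
        n <- sample(4:12, 1)
        m <- mkExpr(rnorm(n * 8), n, 8)
        cm <- correlationMatrix(m)
        k <- sample(1:(n - 1), 1)
        nb <- knnNeighbors(cm, k = k)
        r <- corValues(cm)
        for (g in rownames(r)) {
            row <- r[g, setdiff(rownames(r), g)]
            ord <- names(row)[order(-row, names(row))][1:k]
            expect_identical(neighborsOf(nb, g)$neighbor_id, ord)
        }
    }
})
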