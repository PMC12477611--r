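# Intra-/inter-omics feature learning: label loss, common space,
# commonality constraint, joint representation, spatial regulariser.

test_that("omics label loss hits ln 2 for an uninformative head and 0 for a perfect one", {
    set.seed(31)
    EA1 <- matrix(rnorm(12), 4, 3)
    EA2 <- matrix(rnorm(12), 4, 3)
    headZero <- list(W = matrix(0, 3, 2), b = c(0, 0))
    expect_equal(omicsLabelLoss(EA1, EA2, headZero), log(2),
                 tolerance = 1e-12)

    # embeddings separated along the first dimension, head reads it out
    EA1s <- cbind(-5, matrix(rnorm(8), 4, 2))
    EA2s <- cbind(5, matrix(rnorm(8), 4, 2))
    headSep <- list(W = rbind(c(-10, 10), c(0, 0), c(0, 0)), b = c(0, 0))
    expect_lt(omicsLabelLoss(EA1s, EA2s, headSep), 1e-8)
})

test_that("omics label loss matches a hand-computed log-probability table", {
    # head produces fixed logits; compute -mean(log p_true) by hand
    EA1 <- matrix(c(1, 0, 0, 2), 2, 2)   # rows (1,0), (0,2), label 0
    EA2 <- matrix(c(0, 1, 3, 0), 2, 2)   # rows (0,3), (1,0), label 1
    head <- list(W = rbind(c(0.5, -0.5), c(-1, 1)), b = c(0.1, -0.1))
    logits <- rbind(EA1, EA2) %*% head$W
    logits <- sweep(logits, 2, head$b, `+`)
    p <- exp(logits) / rowSums(exp(logits))
    expected <- -mean(log(c(p[1:2, 1], p[3:4, 2])))
    expect_equal(omicsLabelLoss(EA1, EA2, head), expected,
                 tolerance = 1e-9)
})

test_that("mixed embeddings cannot be classified below ln 2 by any fixed head", {
    # identical row distributions in both roles: every head scores >= ln 2
    set.seed(32)
    E <- matrix(rnorm(40), 10, 4)
    for (rep in 1:10) {
        head <- list(W = matrix(rnorm(8), 4, 2), b = rnorm(2))
        expect_gte(omicsLabelLoss(E, E, head), log(2) - 1e-10)
    }
})

test_that("common-space projection is the clamped affine map", {
    E <- matrix(abs(rnorm(12)), 4, 3)
    expect_equal(projectCommon(E, diag(3), rep(0, 3)), E)
    expect_equal(projectCommon(matrix(0, 2, 2), diag(2), c(-1, -1)),
                 matrix(0, 2, 2))
    set.seed(33)
    W <- matrix(rnorm(9), 3, 3); b <- rnorm(3)
    X <- matrix(rnorm(15), 5, 3)
    expect_equal(projectCommon(X, W, b),
                 pmax(sweep(X %*% W, 2, b, `+`), 0), tolerance = 1e-12)
    expect_true(all(projectCommon(X, W, b) >= 0))
})

test_that("fusing common projections is a row-wise affine map of the concatenation", {
    set.seed(34)
    C1 <- matrix(rnorm(8), 4, 2); C2 <- matrix(rnorm(8), 4, 2)
    Wsel <- rbind(diag(2), matrix(0, 2, 2))
    expect_equal(fuseCommon(C1, C2, Wsel, c(0, 0)), C1)
    Wavg <- rbind(diag(2), diag(2)) / 2
    expect_equal(fuseCommon(C1, C2, Wavg, c(0, 0)), (C1 + C2) / 2)
    W <- matrix(rnorm(8), 4, 2); b <- rnorm(2)
    expect_equal(fuseCommon(C1, C2, W, b),
                 sweep(cbind(C1, C2) %*% W, 2, b, `+`), tolerance = 1e-12)
})

test_that("commonality loss vanishes iff row-normalised Grams coincide", {
    set.seed(35)
    C <- matrix(rnorm(20), 5, 4)
    expect_equal(commonalityLoss(C, C), 0)
    for (rep in 1:5) {
        R <- randomOrthogonal(4)
        expect_lt(commonalityLoss(C, C %*% R), 1e-12)
    }
    # explicit 2x2 case against brute-force computation
    C1 <- rbind(c(1, 0), c(1, 1))
    C2 <- rbind(c(0, 2), c(3, 0))
    n1 <- C1 / sqrt(rowSums(C1^2))
    n2 <- C2 / sqrt(rowSums(C2^2))
    expected <- sum((n1 %*% t(n1) - n2 %*% t(n2))^2) / 4
    expect_equal(commonalityLoss(C1, C2), expected, tolerance = 1e-12)
    expect_gt(expected, 0)
    # zero rows normalise to zero rows rather than NaN
    expect_false(is.nan(commonalityLoss(rbind(c(0, 0), c(1, 1)),
                                        rbind(c(1, 0), c(0, 1)))))
})

test_that("joint representation is the stated weighted sum", {
    set.seed(36)
    EA1 <- matrix(rnorm(6), 2, 3); EA2 <- matrix(rnorm(6), 2, 3)
    EC <- matrix(rnorm(6), 2, 3)
    expect_equal(combineRepresentations(EA1, EA2, EC,
                                        fusionWeights(1, 0, 0)), EA1)
    w <- fusionWeights(0.2, 0.5, 0.4)
    expect_equal(combineRepresentations(EA1, EA1, EA1, w),
                 (0.2 + 0.5 + 0.4) * EA1)
    expect_equal(combineRepresentations(EA1, EA2, EC, w),
                 0.2 * EA1 + 0.5 * EA2 + 0.4 * EC, tolerance = 1e-12)
    expect_error(combineRepresentations(EA1, EA2, matrix(0, 3, 3)),
                 "shapes differ")
})

test_that("spatial regulariser obeys its closed-form small cases", {
    # identical embeddings: Q = 1 everywhere, loss 0
    P <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
    Zsame <- rbind(c(1, 2), c(1, 2))
    expect_equal(spatialRegularization(P, Zsame), 0)

    # no neighbours at all: loss 0
    expect_equal(spatialRegularization(matrix(0, 3, 3),
                                       matrix(rnorm(6), 3, 2)), 0)

    # N = 2: loss = 2 p (1 - q) / 4 with q = exp(-d^2/(2 sigma^2));
    # the median pairwise distance of two points is their distance, so
    # q = exp(-1/2)
    Z2 <- rbind(c(0, 0), c(3, 4))
    q <- exp(-1 / 2)
    expect_equal(spatialRegularization(P, Z2), 2 * 0.8 * (1 - q) / 4,
                 tolerance = 1e-12)

    # invariant under global translation of Z
    set.seed(37)
    co <- matrix(runif(20), 10, 2)
    g <- buildSpatialGraph(CoordinateTable(co), kNeighbors = 3)
    Pm <- as.matrix(graphWeights(g))
    Z <- matrix(rnorm(30), 10, 3)
    Zt <- sweep(Z, 2, c(5, -3, 100), `+`)
    expect_equal(spatialRegularization(Pm, Z),
                 spatialRegularization(Pm, Zt), tolerance = 1e-9)

    # literal mode weights by raw distances
    D <- as.matrix(dist(co))
    expect_gte(spatialRegularization(D, Z, mode = "literal"), 0)
    expect_equal(spatialRegularization(D, rbind(Z[1, ])[rep(1, 10), ],
                                       mode = "literal"), 0)
})
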