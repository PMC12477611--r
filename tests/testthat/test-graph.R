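# Gaussian-kernel spatial graph, its normalisation and multi-slice
# assembly.

test_that("kernel weights on a 3x3 unit grid match direct evaluation", {
    ct <- CoordinateTable(expand.grid(x = 0:2, y = 0:2))
    g <- buildSpatialGraph(ct, lambda = 1, kNeighbors = 8)
    W <- as.matrix(graphWeights(g))
    # independent oracle: evaluate the kernel over all 36 pairs
    pos <- ct@positions
    expW <- matrix(0, 9, 9)
    for (i in 1:9) for (j in 1:9) {
        if (i != j)
            expW[i, j] <- exp(-sum((pos[i, ] - pos[j, ])^2) / 2)
    }
    expect_equal(unname(W), expW, tolerance = 1e-12)
    # spot-checks forced analytically by the kernel
    expect_equal(W[1, 2], exp(-0.5), tolerance = 1e-12) # axial, d = 1
    expect_equal(W[1, 5], exp(-1), tolerance = 1e-12)   # diagonal, d = sqrt(2)
})

test_that("coincident spots get weight 1 and d = lambda*sqrt(2) gives exp(-1)", {
    co <- rbind(c(0, 0), c(0, 0), c(3, 4))
    g <- buildSpatialGraph(CoordinateTable(co), lambda = 2, kNeighbors = 2)
    W <- as.matrix(graphWeights(g))
    expect_equal(W[1, 2], 1)
    lam <- 1.7
    co2 <- rbind(c(0, 0), c(lam * sqrt(2), 0), c(10, 10))
    g2 <- buildSpatialGraph(CoordinateTable(co2), lambda = lam,
                            kNeighbors = 2)
    expect_equal(as.matrix(graphWeights(g2))[1, 2], exp(-1),
                 tolerance = 1e-12)
})

test_that("too few spots for the requested degree is a clear error", {
    expect_error(buildSpatialGraph(cbind(0:2, 0:2), kNeighbors = 6),
                 "kNeighbors \\+ 1")
})

test_that("normalisation matches hand computation and handles no edges", {
    # 2 coincident spots: A12 = 1, Dtilde = diag(2,2) -> all entries 1/2
    g <- buildSpatialGraph(rbind(c(0, 0), c(0, 0)), kNeighbors = 1)
    expect_equal(as.matrix(graphNormalized(g)),
                 matrix(0.5, 2, 2), tolerance = 1e-12)
    # edgeless graph normalises to the identity
    W0 <- methods::as(Matrix::Matrix(0, 3, 3, sparse = TRUE),
                      "CsparseMatrix")
    g0 <- methods::new("SpatialGraph", weights = W0,
                       normalized = methods::as(Matrix::Matrix(0, 0, 0),
                                                "CsparseMatrix"),
                       lambda = 1, kNeighbors = 1L,
                       spotIds = c("a", "b", "c"))
    expect_equal(as.matrix(graphNormalized(normalizeAdjacency(g0))),
                 diag(3), tolerance = 1e-12)
})

test_that("graph and normalised operator are symmetric with bounded spectrum", {
    set.seed(42)
    for (rep in 1:5) {
        n <- sample(10:30, 1)
        co <- matrix(runif(2 * n, 0, 10), n)
        g <- buildSpatialGraph(CoordinateTable(co), kNeighbors = 4)
        W <- graphWeights(g); S <- graphNormalized(g)
        expect_lt(max(abs(W - Matrix::t(W))), 1e-9)
        expect_lt(max(abs(S - Matrix::t(S))), 1e-9)
        expect_true(all(W@x >= 0 & W@x <= 1))
        # spectral radius by power iteration
        v <- rnorm(n)
        for (it in 1:200) { v <- as.numeric(S %*% v); v <- v / sqrt(sum(v^2)) }
        lam <- sum(v * as.numeric(S %*% v))
        expect_lte(abs(lam), 1 + 1e-6)
    }
})

test_that("weights decrease with distance and increase with lambda", {
    co <- cbind(c(0, 1, 2.5, 6, 7, 9), rep(0, 6))
    g1 <- buildSpatialGraph(CoordinateTable(co), lambda = 1, kNeighbors = 5)
    W1 <- as.matrix(graphWeights(g1))
    d <- as.matrix(dist(co))
    for (rep in 1:20) {
        trip <- sample(6, 3)
        i <- trip[1]; j <- trip[2]; k <- trip[3]
        if (d[i, j] < d[i, k])
            expect_gt(W1[i, j], W1[i, k])
    }
    g2 <- buildSpatialGraph(CoordinateTable(co), lambda = 3, kNeighbors = 5)
    W2 <- as.matrix(graphWeights(g2))
    expect_true(all(W2[W1 > 0] >= W1[W1 > 0]))
})

test_that("block-diagonal assembly has no cross-slice edges and commutes with normalisation", {
    co1 <- CoordinateTable(rbind(c(0, 0), c(1, 0)), spotIds = c("a1", "a2"))
    co2 <- CoordinateTable(rbind(c(0, 0), c(2, 0)), spotIds = c("b1", "b2"))
    g1 <- buildSpatialGraph(co1, lambda = 1, kNeighbors = 1)
    g2 <- buildSpatialGraph(co2, lambda = 1, kNeighbors = 1)
    gb <- blockDiagGraph(list(g1, g2))
    Wb <- as.matrix(graphWeights(gb))
    expect_equal(unname(Wb[1:2, 3:4]), matrix(0, 2, 2))
    expect_equal(unname(Wb[3:4, 1:2]), matrix(0, 2, 2))
    # normalisation of the assembly == assembly of normalisations
    Nb <- as.matrix(graphNormalized(gb))
    Nsep <- as.matrix(Matrix::bdiag(graphNormalized(g1),
                                    graphNormalized(g2)))
    expect_lt(max(abs(Nb - Nsep)), 1e-9)
    # single graph passes through unchanged
    expect_identical(blockDiagGraph(list(g1)), g1)
    expect_error(blockDiagGraph(list()), "non-empty")
})

test_that("multi-slice coordinates build a block-diagonal graph directly", {
    co <- CoordinateTable(rbind(c(0, 0), c(1, 0), c(0, 0), c(1, 0)),
                          spotIds = paste0("s", 1:4),
                          sliceIds = c("A", "A", "B", "B"))
    g <- buildSpatialGraph(co, lambda = 1, kNeighbors = 1)
    W <- as.matrix(graphWeights(g))
    expect_equal(unname(W[1:2, 3:4]), matrix(0, 2, 2))
    expect_gt(W[1, 2], 0)
    expect_gt(W[3, 4], 0)
})

test_that("edge list export lists each undirected edge once with its weight", {
    g <- buildSpatialGraph(rbind(c(0, 0), c(1, 0), c(5, 5)), lambda = 1,
                           kNeighbors = 2)
    el <- graphEdgeList(g)
    expect_setequal(names(el), c("i", "j", "weight"))
    W <- as.matrix(graphWeights(g))
    expect_equal(nrow(el), sum(W > 0) / 2)
    f <- file.path(tempdir(), "edges.tsv")
    graphEdgeList(g, f)
    expect_equal(read.delim(f)$weight, el$weight, tolerance = 1e-12)
})
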