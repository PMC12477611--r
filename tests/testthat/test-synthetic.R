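# Synthetic generators: domain geometry, generative moments, and the
# complementary benchmark's construction guarantees.

test_that("stripe and block geometries split the lattice as stated", {
    sp <- syntheticSpec(gridShape = c(10L, 10L), nDomains = 2L,
                        geometry = "stripes")
    d <- generateDomains(sp)
    expect_equal(unname(table(d$labels)), c(50L, 50L), ignore_attr = TRUE)
    # left/right contiguity: label is a function of the x coordinate alone
    x <- d$coords@positions[, 1]
    expect_true(all(d$labels[x <= 5] == 1) && all(d$labels[x > 5] == 2))

    spb <- syntheticSpec(gridShape = c(20L, 20L), nDomains = 4L,
                         geometry = "blocks")
    db <- generateDomains(spb)
    pos <- db$coords@positions
    quad <- 1L + (pos[, 1] > 10) + 2L * (pos[, 2] > 10)
    expect_equal(db$labels, as.integer(quad))
})

test_that("voronoi domains are deterministic per seed and occupy every label", {
    sp <- syntheticSpec(gridShape = c(15L, 15L), nDomains = 4L,
                        geometry = "voronoi", seed = 5L)
    d1 <- generateDomains(sp)
    d2 <- generateDomains(sp)
    expect_identical(d1$labels, d2$labels)
    expect_equal(sort(unique(d1$labels)), 1:4)
    expect_error(generateDomains(syntheticSpec(gridShape = c(2L, 2L),
                                               nDomains = 5L)),
                 "more domains")
})

test_that("RNA draws match NB / ZINB moments", {
    sp <- syntheticSpec(gridShape = c(100L, 100L), nDomains = 2L,
                        rna = list(nGenes = 1L, markersPerDomain = 0L,
                                   muBase = 5, fold = 1, theta = 2,
                                   dropout = 0))
    set.seed(100)
    x <- simulateRNA(rep(1L, 10000L), sp)
    expect_equal(mean(x), 5, tolerance = 0.05)            # within 5%
    expect_equal(var(as.numeric(x)), 5 + 25 / 2, tolerance = 0.05)
    # dropout scales the mean by (1 - pi)
    sp2 <- syntheticSpec(gridShape = c(100L, 100L), nDomains = 2L,
                         rna = list(nGenes = 1L, markersPerDomain = 0L,
                                    muBase = 5, fold = 1, theta = 2,
                                    dropout = 0.3))
    set.seed(101)
    x2 <- simulateRNA(rep(1L, 10000L), sp2)
    se <- sqrt(var(as.numeric(x2)) / 10000)
    expect_lt(abs(mean(x2) - 0.7 * 5), 3 * se)
    # pi = 1 zeroes everything
    sp3 <- syntheticSpec(rna = list(dropout = 1))
    set.seed(102)
    expect_true(all(simulateRNA(rep(1L, 50L), sp3) == 0))
})

test_that("accessibility draws are binary with the planted frequency", {
    sp <- syntheticSpec(atac = list(nPeaks = 1L, markersPerDomain = 0L,
                                    pOn = 0.8, pOff = 0.3))
    set.seed(103)
    x <- simulateATAC(rep(1L, 10000L), sp)
    expect_true(all(x %in% c(0, 1)))
    expect_lt(abs(mean(x) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
    sp0 <- syntheticSpec(atac = list(nPeaks = 2L, markersPerDomain = 1L,
                                     pOn = 1, pOff = 0))
    set.seed(104)
    x0 <- simulateATAC(rep(1L, 20L), sp0)
    expect_true(all(x0[, 1] == 1) && all(x0[, 2] == 0))
})

test_that("ADT draws follow the background/foreground mixture", {
    # pure background (bgProb = 1): count mean equals the log-normal mean
    sp <- syntheticSpec(adt = list(nProteins = 1L, markersPerDomain = 0L,
                                   bgMeanlog = log(5), bgSdlog = 0.4,
                                   fold = 5, phi = 3, bgProb = 1))
    set.seed(105)
    x <- simulateADT(rep(1L, 10000L), sp)
    expected <- exp(log(5) + 0.4^2 / 2)
    se <- sqrt(var(as.numeric(x)) / 10000)
    expect_lt(abs(mean(x) - expected), 3 * se)
    expect_true(all(x >= 0 & x == round(x)))

    # fold = 1: background and foreground indistinguishable; the fitted
    # background prior recovers the single log-scale location
    sp1 <- syntheticSpec(adt = list(nProteins = 1L, markersPerDomain = 1L,
                                    bgMeanlog = log(20), bgSdlog = 0.3,
                                    fold = 1, phi = 50, bgProb = 0.5))
    set.seed(106)
    x1 <- simulateADT(rep(1L, 2000L), sp1)
    prior <- fitGMMPrior(x1)
    expect_lt(abs(prior$mPrior[1] - mean(log1p(x1))), 0.35)
})

test_that("generators are bitwise reproducible per seed", {
    sp <- syntheticSpec(seed = 9L)
    lab <- generateDomains(sp)$labels
    set.seed(1); a <- simulateRNA(lab, sp)
    set.seed(1); b <- simulateRNA(lab, sp)
    expect_identical(a, b)
    b1 <- makeComplementaryBenchmark(seed = 3L)
    b2 <- makeComplementaryBenchmark(seed = 3L)
    expect_identical(b1$pair@omics1@raw, b2$pair@omics1@raw)
    expect_identical(b1$truth, b2$truth)
})

test_that("complementary benchmark bounds single-modality information", {
    b <- makeComplementaryBenchmark(seed = 2L)
    # balanced 2x2 blocks
    expect_equal(unname(table(b$truth)), rep(506L, 4), ignore_attr = TRUE)
    expect_equal(length(b$truth), 2024L)

    # k-means on modality-1 PCA alone cannot resolve 4 domains ...
    pc <- stats::prcomp(b$pair@omics1@encodedInput, rank. = 10)$x
    set.seed(11)
    k4 <- stats::kmeans(pc, centers = 4, nstart = 10)$cluster
    expect_lte(adjustedRandIndex(k4, b$truth), 0.6)

    # ... but resolves its own two-way split essentially perfectly
    rnaSplit <- ifelse(b$truth %in% c(1, 2), 1, 2)
    set.seed(12)
    k2 <- stats::kmeans(pc, centers = 2, nstart = 10)$cluster
    expect_gte(adjustedRandIndex(k2, rnaSplit), 0.9)

    # modality 2 encodes the orthogonal split
    pc2 <- stats::prcomp(b$pair@omics2@encodedInput, rank. = 10)$x
    atacSplit <- ifelse(b$truth %in% c(1, 3), 1, 2)
    set.seed(13)
    k2b <- stats::kmeans(pc2, centers = 2, nstart = 10)$cluster
    expect_gte(adjustedRandIndex(k2b, atacSplit), 0.9)
})
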