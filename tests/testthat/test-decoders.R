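# Probabilistic decoders: parameter heads, likelihood kernels against
# independent oracles, GMM background prior, and the loss aggregator.

# independent ZINB log-pmf built on stats::dnbinom
zinbLogPmfOracle <- function(x, pi, mu, theta) {
    nb <- stats::dnbinom(x, size = theta, mu = mu)
    log(ifelse(x == 0, pi + (1 - pi) * nb, (1 - pi) * nb))
}

nbMixLogPmfOracle <- function(x, nuB, nuF, pi, phi) {
    log(pi * stats::dnbinom(x, size = phi, mu = nuB) +
        (1 - pi) * stats::dnbinom(x, size = phi, mu = nuF))
}

test_that("zero-weight ZINB heads give pi = 0.5, mu = theta = 1", {
    Z <- matrix(rnorm(10), 5, 2)
    p <- zinbParams(Z, zeroDecoderParams("rna", 2, 3))
    expect_equal(unname(p$pi), matrix(0.5, 5, 3))
    expect_equal(unname(p$mu), matrix(1, 5, 3))
    expect_equal(unname(p$theta), matrix(1, 5, 3))
})

test_that("ZINB heads stay in range and match the composed affine oracle", {
    set.seed(41)
    Z <- matrix(rnorm(8), 4, 2)
    par <- smofuse:::initDecoderParams("rna", 2, 3)
    p <- zinbParams(Z, par)
    expect_true(all(p$pi > 0 & p$pi < 1))
    expect_true(all(p$mu > 0) && all(p$theta > 0))
    H <- sweep(Z %*% par$Wd, 2, par$bd, `+`)
    H <- H * (H > 0) + (exp(pmin(H, 0)) - 1) * (H <= 0)
    expect_equal(unname(p$mu),
                 unname(exp(sweep(H %*% par$Wmu, 2, par$bmu, `+`))),
                 tolerance = 1e-9)
})

test_that("ZINB NLL agrees with the dnbinom oracle and degenerate cases", {
    # pi = 1 makes zeros certain
    expect_equal(zinbNLL(matrix(0, 2, 2), pi = 1 - 1e-12, mu = 3,
                         theta = 2), 0, tolerance = 1e-9)
    # pi = 0 reduces to plain NB
    set.seed(42)
    x <- matrix(rpois(20, 4), 4, 5)
    mu <- matrix(runif(20, 0.5, 8), 4, 5)
    th <- matrix(runif(20, 0.5, 5), 4, 5)
    expect_equal(zinbNLL(x, 1e-300, mu, th),
                 -sum(stats::dnbinom(x, size = th, mu = mu, log = TRUE)),
                 tolerance = 1e-6)
    expect_error(zinbNLL(matrix(-1), 0.5, 1, 1), "non-negative integer")
    expect_error(zinbNLL(matrix(1.5), 0.5, 1, 1), "non-negative integer")
})

test_that("Bernoulli head is monotone in its logit and BCE matches hand sums", {
    Z <- matrix(rnorm(6), 3, 2)
    p0 <- bernoulliParams(Z, zeroDecoderParams("atac", 2, 4))
    expect_equal(unname(p0$p), matrix(0.5, 3, 4))
    par <- smofuse:::initDecoderParams("atac", 2, 4)
    pa <- bernoulliParams(Z, par)$p
    par$bp <- par$bp + 1
    pb <- bernoulliParams(Z, par)$p
    expect_true(all(pb > pa))

    x <- matrix(rbinom(12, 1, 0.5), 3, 4)
    expect_equal(atacBCE(x, matrix(0.5, 3, 4)), 12 * log(2),
                 tolerance = 1e-12)
    pexact <- pmin(pmax(x, 1e-7), 1 - 1e-7)
    expect_lt(atacBCE(x, pexact), 1e-4)
    set.seed(43)
    pr <- matrix(runif(12, 0.05, 0.95), 3, 4)
    expect_equal(atacBCE(x, pr),
                 -sum(x * log(pr) + (1 - x) * log(1 - pr)),
                 tolerance = 1e-10)
    expect_error(atacBCE(matrix(2, 1, 1), matrix(0.5)), "binary")
})

test_that("GMM prior recovers a planted background component", {
    set.seed(44)
    # two well-separated clusters on the log1p scale, means 1 and 4
    vals <- c(expm1(rnorm(1000, 1, 0.4)), expm1(rnorm(1000, 4, 0.4)))
    vals <- pmax(vals, 0)
    prior <- fitGMMPrior(cbind(vals))
    se3 <- 3 * 0.4 / sqrt(1000)
    expect_lt(abs(prior$mPrior[1] - 1), se3 + 0.05)
    expect_false(prior$fallback[1])

    # single cluster: lower component stays near the sample mean
    one <- pmax(expm1(rnorm(1000, 2, 0.3)), 0)
    prior1 <- fitGMMPrior(cbind(one))
    expect_lt(abs(prior1$mPrior[1] - mean(log1p(one))), 0.3)

    # constant counts use the documented fallback
    priorC <- fitGMMPrior(cbind(rep(5, 50)))
    expect_true(priorC$fallback[1])
    expect_equal(priorC$mPrior[1], log1p(5))
    expect_equal(priorC$sigmaPrior[1], 0.5 * log1p(5) + 0.1)
})

test_that("ADT heads respect the foreground/background identity and sampling contract", {
    Z <- matrix(rnorm(10), 5, 2)
    p0 <- adtParams(Z, zeroDecoderParams("adt", 2, 3))
    expect_equal(unname(p0$alphaAdt), matrix(log(2), 5, 3),
                 tolerance = 1e-12)
    par <- smofuse:::initDecoderParams("adt", 2, 3)
    pe <- adtParams(Z, par)
    expect_equal(pe$nuF / pe$nuB, 1 + pe$alphaAdt, tolerance = 1e-12)
    expect_true(all(pe$nuF >= pe$nuB))
    # evaluation mode uses the analytic log-normal mean
    expect_equal(pe$nuB, pmin(pmax(exp(pe$mB + pe$sigmaB^2 / 2),
                                   1e-5), 1e6), tolerance = 1e-12)
    # sampling path is reproducible under a fixed seed
    set.seed(7); s1 <- adtParams(Z, par, sample = TRUE)
    set.seed(7); s2 <- adtParams(Z, par, sample = TRUE)
    expect_identical(s1$nuB, s2$nuB)
})

test_that("NB mixture NLL collapses correctly and matches the oracle", {
    set.seed(45)
    x <- matrix(rpois(20, 6), 4, 5)
    nuB <- matrix(runif(20, 1, 4), 4, 5)
    nuF <- matrix(runif(20, 5, 15), 4, 5)
    phi <- runif(5, 0.5, 4)
    PHI <- matrix(phi, 4, 5, byrow = TRUE)
    # pi = 1 -> background NB; pi = 0 -> foreground NB
    expect_equal(nbMixtureNLL(x, nuB, nuF, 1 - 1e-12, phi),
                 -sum(stats::dnbinom(x, size = PHI, mu = nuB, log = TRUE)),
                 tolerance = 1e-6)
    expect_equal(nbMixtureNLL(x, nuB, nuF, 1e-12, phi),
                 -sum(stats::dnbinom(x, size = PHI, mu = nuF, log = TRUE)),
                 tolerance = 1e-6)
    # identical components: any pi gives the single NB
    for (pi in c(0.1, 0.5, 0.9))
        expect_equal(nbMixtureNLL(x, nuB, nuB, pi, phi),
                     -sum(stats::dnbinom(x, size = PHI, mu = nuB,
                                         log = TRUE)),
                     tolerance = 1e-8)
})

test_that("KL between lognormal posterior and prior is the Gaussian closed form", {
    set.seed(46)
    m <- matrix(rnorm(6), 2, 3); s <- matrix(runif(6, 0.5, 2), 2, 3)
    mp <- rnorm(3); sp <- runif(3, 0.5, 2)
    MP <- matrix(mp, 2, 3, byrow = TRUE); SP <- matrix(sp, 2, 3, byrow = TRUE)
    expected <- sum(log(SP / s) + (s^2 + (m - MP)^2) / (2 * SP^2) - 0.5)
    expect_equal(klLognormal(m, s, mp, sp), expected, tolerance = 1e-12)
    expect_equal(klLognormal(MP, SP, mp, sp), 0, tolerance = 1e-12)
})

test_that("generic decoder loss bottoms out at the target entropy", {
    x <- matrix(c(0, 1, 1, 0), 2, 2)
    expect_equal(genericReconstructionLoss(x, matrix(0.5, 2, 2)),
                 4 * log(2), tolerance = 1e-12)
    expect_lt(genericReconstructionLoss(x, pmin(pmax(x, 1e-7), 1 - 1e-7)),
              1e-4)
    set.seed(47)
    xc <- matrix(runif(6), 2, 3); xh <- matrix(runif(6, 0.1, 0.9), 2, 3)
    expect_equal(genericReconstructionLoss(xc, xh),
                 -sum(xc * log(xh) + (1 - xc) * log(1 - xh)),
                 tolerance = 1e-10)
    expect_error(genericReconstructionLoss(matrix(2, 1, 1), matrix(0.5)),
                 "preprocessOther")
})

test_that("total reconstruction loss sums the active modalities", {
    expect_equal(totalReconstructionLoss(list(rna = 5)), 5)
    expect_equal(totalReconstructionLoss(list(rna = 5, atac = 2.5)), 7.5)
    expect_error(totalReconstructionLoss(list()), "at least one")
})
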