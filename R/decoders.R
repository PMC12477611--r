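# Omics-specific probabilistic decoders. Each modality maps the joint
# representation Z through a shared hidden stack f_D (one elu layer) and
# linear heads to its likelihood parameters; the reconstruction loss is
# the summed negative log-likelihood. All likelihoods are computed in log
# space; mixtures use log-sum-exp. Exported functions are pure; training
# reuses the same kernels through the gradient tape.

# mclust is imported wholesale: Mclust() resolves helpers such as
# mclustBIC() by evaluation in the calling frame, which only works when
# they are visible from this namespace.
#' @import mclust
NULL

.DEC_HIDDEN <- 64L

# Initialise decoder parameters for one modality (draws from current RNG).
initDecoderParams <- function(modality, g, d, hidden = .DEC_HIDDEN) {
    base <- list(Wd = glorotUniform(g, hidden), bd = numeric(hidden))
    heads <- switch(modality,
        rna = list(Wpi = glorotUniform(hidden, d), bpi = numeric(d),
                   Wmu = glorotUniform(hidden, d), bmu = numeric(d),
                   Wth = glorotUniform(hidden, d), bth = numeric(d)),
        atac = list(Wp = glorotUniform(hidden, d), bp = numeric(d)),
        adt = list(Wm = glorotUniform(hidden, d), bm = numeric(d),
                   Ws = glorotUniform(hidden, d), bs = numeric(d),
                   Wpi = glorotUniform(hidden, d), bpi = numeric(d),
                   Wa = glorotUniform(hidden, d), ba = numeric(d),
                   logphi = numeric(d)),
        other = list(Wo = glorotUniform(hidden, d), bo = numeric(d)))
    c(base, heads)
}

.decHidden <- function(Z, params) {
    .activate(sweep(Z %*% params$Wd, 2, params$bd, `+`), "elu")
}

#' ZINB decoder parameters
#'
#' `pi = sigmoid(W_pi f_D(Z))`, `mu = exp(W_mu f_D(Z))`,
#' `theta = exp(W_th f_D(Z))` with the exp outputs clamped to
#' \[1e-5, 1e6\]. `f_D` is a shared single elu hidden layer. With all
#' weights zero this yields pi = 0.5, mu = theta = 1 everywhere.
#'
#' @param Z N x g joint representation.
#' @param params decoder parameter list (see [initDecoderParams()] fields
#'   `Wd, bd, Wpi, bpi, Wmu, bmu, Wth, bth`).
#' @return List with N x d matrices `pi` (in (0,1)), `mu`, `theta`
#'   (positive).
#' @export
zinbParams <- function(Z, params) {
    H <- .decHidden(as.matrix(Z), params)
    list(pi = pmin(pmax(stats::plogis(sweep(H %*% params$Wpi, 2,
                                            params$bpi, `+`)),
                        1e-7), 1 - 1e-7),
         mu = pmin(pmax(exp(sweep(H %*% params$Wmu, 2, params$bmu, `+`)),
                        1e-5), 1e6),
         theta = pmin(pmax(exp(sweep(H %*% params$Wth, 2, params$bth, `+`)),
                           1e-5), 1e6))
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' \eqn{-\sum_i \sum_g \log \mathrm{ZINB}(x \mid \pi, \mu, \theta)} with
#' \eqn{\mathrm{ZINB}(0) = \pi + (1-\pi)\,\mathrm{NB}(0)} and
#' \eqn{\mathrm{ZINB}(x>0) = (1-\pi)\,\mathrm{NB}(x)}; the NB is in
#' mean/dispersion form
#' \eqn{\mathrm{NB}(x \mid \mu,\theta) = \frac{\Gamma(x+\theta)}{\Gamma(\theta)\,x!}
#' \left(\frac{\theta}{\theta+\mu}\right)^\theta
#' \left(\frac{\mu}{\theta+\mu}\right)^x}.
#'
#' @param x N x d matrix of non-negative integer counts.
#' @param pi,mu,theta N x d parameter matrices (or scalars, recycled).
#' @return Scalar total NLL.
#' @export
zinbNLL <- function(x, pi, mu, theta) {
    x <- as.matrix(x)
    expand <- function(p) {
        if (length(p) == 1) matrix(p, nrow(x), ncol(x)) else as.matrix(p)
    }
    tape <- agTape()
    agValue(agZinbNLL(agLeaf(tape, expand(pi)), agLeaf(tape, expand(mu)),
                      agLeaf(tape, expand(theta)), x))
}

#' Bernoulli decoder parameters
#'
#' `p = sigmoid(f_p(f_D(Z)))`, clamped to \[1e-7, 1 - 1e-7\].
#'
#' @param Z N x g joint representation.
#' @param params decoder parameter list (`Wd, bd, Wp, bp`).
#' @return List with N x d matrix `p`.
#' @export
bernoulliParams <- function(Z, params) {
    H <- .decHidden(as.matrix(Z), params)
    list(p = pmin(pmax(stats::plogis(sweep(H %*% params$Wp, 2,
                                           params$bp, `+`)),
                       1e-7), 1 - 1e-7))
}

#' Binary cross-entropy reconstruction loss for accessibility
#'
#' \eqn{\sum_i \sum_q -[x \log p + (1-x)\log(1-p)]} over a strictly binary
#' target.
#'
#' @param x N x d binary matrix; @param p N x d probabilities in (0,1)
#'   (or a list with element `p` as returned by [bernoulliParams()]).
#' @return Scalar total BCE.
#' @export
atacBCE <- function(x, p) {
    if (is.list(p)) p <- p$p
    x <- as.matrix(x)
    if (!all(x %in% c(0, 1)))
        stop("ATAC target must be strictly binary (0/1)")
    tape <- agTape()
    agValue(agBCESum(agLeaf(tape, as.matrix(p)), x))
}

#' Fit the log-normal background prior for ADT counts
#'
#' Per protein, a two-component Gaussian mixture is fitted to
#' `log1p(counts)` and the lower-mean component's mean and standard
#' deviation initialise the log-normal prior on the background intensity.
#' Proteins with (near-)constant counts fall back to
#' `(mean, 0.5 * |mean| + 0.1)`.
#'
#' @param adtCounts N x d non-negative integer count matrix.
#' @return List with numeric vectors `mPrior` and `sigmaPrior` (length d,
#'   `sigmaPrior` floored at 0.01) and `fallback`, a logical vector
#'   marking degenerate proteins.
#' @export
fitGMMPrior <- function(adtCounts) {
    x <- .asDenseCounts(adtCounts)
    d <- ncol(x)
    mPrior <- numeric(d); sigmaPrior <- numeric(d)
    fallback <- logical(d)
    for (p in seq_len(d)) {
        lg <- log1p(x[, p])
        if (stats::sd(lg) < 1e-8) {
            m <- mean(lg)
            mPrior[p] <- m
            sigmaPrior[p] <- 0.5 * abs(m) + 0.1
            fallback[p] <- TRUE
            next
        }
        fit <- tryCatch(
            mclust::Mclust(lg, G = 2, modelNames = "V", verbose = FALSE),
            error = function(e) NULL)
        if (is.null(fit)) {
            mPrior[p] <- mean(lg)
            sigmaPrior[p] <- max(stats::sd(lg), 0.01)
            fallback[p] <- TRUE
        } else {
            lo <- which.min(fit$parameters$mean)
            mPrior[p] <- fit$parameters$mean[lo]
            sigmaPrior[p] <- max(sqrt(fit$parameters$variance$sigmasq[lo]),
                                 0.01)
        }
    }
    list(mPrior = mPrior, sigmaPrior = sigmaPrior, fallback = fallback)
}

#' ADT decoder parameters
#'
#' The posterior over the log background intensity is
#' `lognormal(m_b, sigma_b)` with `m_b = f_m(f_D(Z))` and
#' `sigma_b = exp(f_s(f_D(Z)))`. During training `nu_b` is a
#' reparameterised sample `exp(m_b + sigma_b * eps)`; at evaluation it is
#' the analytic log-normal mean `exp(m_b + sigma_b^2/2)`. The background
#' probability is a sigmoid head, the foreground ratio a softplus head,
#' and `nu_f = (1 + alpha) * nu_b`, which guarantees foreground >=
#' background.
#'
#' @param Z N x g joint representation.
#' @param params decoder parameter list (`Wd, bd, Wm, bm, Ws, bs, Wpi,
#'   bpi, Wa, ba, logphi`).
#' @param sample draw `nu_b` by reparameterised sampling (training mode);
#'   default FALSE (deterministic evaluation mode).
#' @param eps optional N x d matrix of standard-normal draws to use when
#'   `sample = TRUE`; drawn from the current RNG when NULL.
#' @return List with N x d matrices `nuB`, `nuF`, `piAdt`, `alphaAdt`,
#'   `mB`, `sigmaB` and length-d `phi`.
#' @export
adtParams <- function(Z, params, sample = FALSE, eps = NULL) {
    Z <- as.matrix(Z)
    H <- .decHidden(Z, params)
    mB <- sweep(H %*% params$Wm, 2, params$bm, `+`)
    sigmaB <- pmin(pmax(exp(sweep(H %*% params$Ws, 2, params$bs, `+`)),
                        1e-4), 10)
    piAdt <- pmin(pmax(stats::plogis(sweep(H %*% params$Wpi, 2,
                                           params$bpi, `+`)),
                       1e-7), 1 - 1e-7)
    alphaAdt <- log1p(exp(pmin(sweep(H %*% params$Wa, 2, params$ba, `+`),
                               30)))
    if (sample) {
        if (is.null(eps))
            eps <- matrix(stats::rnorm(length(mB)), nrow(mB), ncol(mB))
        nuB <- exp(mB + sigmaB * eps)
    } else {
        nuB <- exp(mB + sigmaB^2 / 2)
    }
    nuB <- pmin(pmax(nuB, 1e-5), 1e6)
    list(nuB = nuB, nuF = (1 + alphaAdt) * nuB, piAdt = piAdt,
         alphaAdt = alphaAdt, mB = mB, sigmaB = sigmaB,
         phi = pmin(pmax(exp(params$logphi), 1e-4), 1e4))
}

#' Negative-binomial mixture negative log-likelihood
#'
#' \eqn{-\sum \log[\pi\,\mathrm{NB}(x \mid \nu_b, \varphi) +
#' (1-\pi)\,\mathrm{NB}(x \mid \nu_f, \varphi)]} via log-sum-exp, with a
#' per-protein dispersion \eqn{\varphi}.
#'
#' @param x N x d matrix of non-negative integer counts.
#' @param nuB,nuF,piAdt N x d parameter matrices (scalars recycled).
#' @param phi length-d positive dispersion vector (scalar recycled).
#' @return Scalar total NLL (excluding any KL regulariser; training adds
#'   the posterior/prior KL separately).
#' @export
nbMixtureNLL <- function(x, nuB, nuF, piAdt, phi) {
    x <- as.matrix(x)
    expand <- function(p) {
        if (length(p) == 1) matrix(p, nrow(x), ncol(x)) else as.matrix(p)
    }
    if (length(phi) == 1) phi <- rep(phi, ncol(x))
    tape <- agTape()
    agValue(agNBMixNLL(agLeaf(tape, expand(nuB)), agLeaf(tape, expand(nuF)),
                       agLeaf(tape, expand(piAdt)),
                       agLeaf(tape, as.numeric(phi)), x))
}

#' KL divergence between posterior and prior log-normal background
#'
#' Closed-form Gaussian KL on the log scale, summed over all entries.
#'
#' @param mB,sigmaB N x d posterior parameters.
#' @param mPrior,sigmaPrior length-d prior parameters.
#' @return Non-negative scalar.
#' @export
klLognormal <- function(mB, sigmaB, mPrior, sigmaPrior) {
    tape <- agTape()
    agValue(agKLLognormal(agLeaf(tape, as.matrix(mB)),
                          agLeaf(tape, as.matrix(sigmaB)),
                          as.numeric(mPrior), as.numeric(sigmaPrior)))
}

#' Generic cross-entropy reconstruction loss
#'
#' For "other" omics scaled to \[0,1\]: the reconstruction is
#' `sigmoid(f_D(Z))` and the loss the summed elementwise binary
#' cross-entropy. The minimum over reconstructions is the total entropy of
#' the target.
#'
#' @param x N x d target matrix with entries in \[0,1\].
#' @param xhat N x d reconstruction with entries in (0,1); alternatively
#'   pass `Z` and `params` to compute it.
#' @param Z,params optional joint representation and decoder parameters
#'   (`Wd, bd, Wo, bo`) used when `xhat` is missing.
#' @return Scalar total cross-entropy.
#' @export
genericReconstructionLoss <- function(x, xhat = NULL, Z = NULL,
                                      params = NULL) {
    x <- as.matrix(x)
    if (min(x) < 0 || max(x) > 1)
        stop("target must lie in [0,1]; run preprocessOther() first")
    if (is.null(xhat)) {
        H <- .decHidden(as.matrix(Z), params)
        xhat <- pmin(pmax(stats::plogis(sweep(H %*% params$Wo, 2,
                                              params$bo, `+`)),
                          1e-7), 1 - 1e-7)
    }
    tape <- agTape()
    agValue(agBCESum(agLeaf(tape, as.matrix(xhat)), x))
}

#' Total reconstruction loss
#'
#' Sum of the active modalities' reconstruction losses; inactive
#' modalities contribute nothing.
#'
#' @param losses named or unnamed list/vector of per-modality scalar
#'   losses (at least one).
#' @return Scalar sum.
#' @export
totalReconstructionLoss <- function(losses) {
    losses <- unlist(losses)
    if (length(losses) == 0)
        stop("at least one active modality is required")
    sum(losses)
}
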