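# Minimal reverse-mode automatic differentiation over dense matrix
# operations. A tape (environment) records nodes in creation order; each
# non-leaf node carries a backward closure mapping the output gradient to
# gradients for its parents. agBackward() sweeps the tape once in reverse.
#
# Only the operations the model needs are implemented, and the likelihood
# losses are single fused nodes with hand-derived vectorised backwards —
# this keeps the tape short (tens of nodes) so all time is spent in BLAS.
# Internal API (not exported): used by the model/training code and
# exercised directly by finite-difference tests.

agTape <- function() {
    env <- new.env(parent = emptyenv())
    env$nodes <- vector("list", 64L)
    env$n <- 0L
    env
}

.agNew <- function(tape, value, parents = list(), backward = NULL) {
    # force the argument promises before allocating this node's id: with
    # lazy evaluation a nested op call inside `value`/`parents` would
    # otherwise be recorded AFTER its consumer, breaking the reverse sweep
    force(parents); force(value)
    id <- tape$n + 1L
    if (id > length(tape$nodes))
        tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$n <- id
    node <- structure(list(tape = tape, id = id, value = value,
                           parents = vapply(parents, function(p) p$id,
                                            integer(1)),
                           backward = backward),
                      class = "agnode")
    tape$nodes[[id]] <- node
    node
}

agIsNode <- function(x) inherits(x, "agnode")

agLeaf <- function(tape, value) .agNew(tape, value)

agValue <- function(x) if (agIsNode(x)) x$value else x

# Reverse sweep from a scalar root; returns list of gradients indexed by
# node id (NULL where no gradient flows).
agBackward <- function(root) {
    tape <- root$tape
    grads <- vector("list", tape$n)
    grads[[root$id]] <- 1
    for (id in seq(root$id, 1L)) {
        node <- tape$nodes[[id]]
        g <- grads[[id]]
        if (is.null(g) || is.null(node$backward)) next
        pg <- node$backward(g)
        for (k in seq_along(node$parents)) {
            if (is.null(pg[[k]])) next
            pid <- node$parents[k]
            grads[[pid]] <- if (is.null(grads[[pid]])) pg[[k]]
                            else grads[[pid]] + pg[[k]]
        }
    }
    grads
}

# ---- elementary ops ---------------------------------------------------

agMatmul <- function(a, b) {
    av <- agValue(a); bv <- agValue(b)
    if (agIsNode(a) && agIsNode(b))
        .agNew(a$tape, av %*% bv, list(a, b),
               function(g) list(g %*% t(bv), crossprod(av, g)))
    else if (agIsNode(a))
        .agNew(a$tape, av %*% bv, list(a), function(g) list(g %*% t(bv)))
    else
        .agNew(b$tape, av %*% bv, list(b), function(g) list(crossprod(av, g)))
}

# constant sparse operator (graph) times node; S must be symmetric
agSpMatmul <- function(S, b) {
    v <- as.matrix(S %*% agValue(b))
    .agNew(b$tape, v, list(b), function(g) list(as.matrix(S %*% g)))
}

agAdd <- function(a, b) {
    .agNew(a$tape, agValue(a) + agValue(b), list(a, b),
           function(g) list(g, g))
}

agAddBias <- function(a, bias) {
    v <- sweep(agValue(a), 2, agValue(bias), `+`)
    .agNew(a$tape, v, list(a, bias),
           function(g) list(g, colSums(g)))
}

agMul <- function(a, b) {
    av <- agValue(a); bv <- agValue(b)
    .agNew(a$tape, av * bv, list(a, b),
           function(g) list(g * bv, g * av))
}

agScale <- function(a, s) {
    .agNew(a$tape, agValue(a) * s, list(a), function(g) list(g * s))
}

agMulC <- function(a, C) {
    .agNew(a$tape, agValue(a) * C, list(a), function(g) list(g * C))
}

agAddC <- function(a, C) {
    .agNew(a$tape, agValue(a) + C, list(a), function(g) list(g))
}

agRelu <- function(a) {
    av <- agValue(a)
    mask <- av > 0
    .agNew(a$tape, av * mask, list(a), function(g) list(g * mask))
}

agElu <- function(a) {
    av <- agValue(a)
    pos <- av > 0
    v <- av * pos + (exp(pmin(av, 0)) - 1) * !pos
    .agNew(a$tape, v, list(a),
           function(g) list(g * (pos + (v + 1) * !pos)))
}

agSigmoid <- function(a, clampEps = 0) {
    v <- stats::plogis(agValue(a))
    if (clampEps > 0) {
        vc <- pmin(pmax(v, clampEps), 1 - clampEps)
        inside <- v > clampEps & v < 1 - clampEps
        .agNew(a$tape, vc, list(a),
               function(g) list(g * v * (1 - v) * inside))
    } else {
        .agNew(a$tape, v, list(a), function(g) list(g * v * (1 - v)))
    }
}

# exp with output clamped to [lo, hi]; gradient zero where clamped
agExp <- function(a, lo = 1e-5, hi = 1e6) {
    v <- exp(pmin(agValue(a), 700))
    vc <- pmin(pmax(v, lo), hi)
    inside <- v > lo & v < hi
    .agNew(a$tape, vc, list(a), function(g) list(g * vc * inside))
}

agSoftplus <- function(a) {
    av <- agValue(a)
    v <- ifelse(av > 30, av, log1p(exp(pmin(av, 30))))
    .agNew(a$tape, v, list(a), function(g) list(g * stats::plogis(av)))
}

agCbind <- function(a, b) {
    av <- agValue(a); bv <- agValue(b)
    na <- ncol(av)
    .agNew(a$tape, cbind(av, bv), list(a, b),
           function(g) list(g[, seq_len(na), drop = FALSE],
                            g[, -seq_len(na), drop = FALSE]))
}

agRbind <- function(a, b) {
    av <- agValue(a); bv <- agValue(b)
    na <- nrow(av)
    .agNew(a$tape, rbind(av, bv), list(a, b),
           function(g) list(g[seq_len(na), , drop = FALSE],
                            g[-seq_len(na), , drop = FALSE]))
}

# weighted sum of matrix nodes with constant scalar weights
agLinComb <- function(nodes, weights) {
    v <- weights[1] * agValue(nodes[[1]])
    for (k in seq_along(nodes)[-1]) v <- v + weights[k] * agValue(nodes[[k]])
    .agNew(nodes[[1]]$tape, v, nodes,
           function(g) lapply(weights, function(w) g * w))
}

# weighted sum of scalar nodes (total loss assembly)
agSumScalars <- function(nodes, weights = rep(1, length(nodes))) {
    v <- sum(vapply(seq_along(nodes),
                    function(k) weights[k] * agValue(nodes[[k]]),
                    numeric(1)))
    .agNew(nodes[[1]]$tape, v, nodes,
           function(g) as.list(g * weights))
}

# ---- fused model-specific ops ----------------------------------------

# Global self-attention: softmax(E E^T / sqrt(g)) E, row-wise softmax with
# max-subtraction. O(N^2 g) forward and backward.
agAttention <- function(E) {
    Ev <- agValue(E)
    g <- ncol(Ev)
    n <- nrow(Ev)
    S <- tcrossprod(Ev) / sqrt(g)
    S <- S - S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
    A <- exp(S)
    A <- A / rowSums(A)
    O <- A %*% Ev
    .agNew(E$tape, O, list(E), function(gr) {
        dA <- tcrossprod(gr, Ev)
        dE <- crossprod(A, gr)
        dS <- A * (dA - rowSums(dA * A))
        dE <- dE + (dS %*% Ev + crossprod(dS, Ev)) / sqrt(g)
        list(dE)
    })
}

# Mean two-class cross-entropy of logits against integer labels (0/1).
agSoftmaxCE <- function(logits, labels) {
    L <- agValue(logits)
    n <- nrow(L)
    M <- apply(L, 1, max)
    LS <- L - M
    lse <- log(rowSums(exp(LS)))
    logp <- LS - lse
    idx <- cbind(seq_len(n), labels + 1L)
    v <- -mean(logp[idx])
    P <- exp(logp)
    .agNew(logits$tape, v, list(logits), function(g) {
        Y <- matrix(0, n, ncol(L))
        Y[idx] <- 1
        list(g * (P - Y) / n)
    })
}

# Summed binary cross-entropy; p must already be clamped into (0,1).
agBCESum <- function(p, x) {
    pv <- agValue(p)
    v <- -sum(x * log(pv) + (1 - x) * log1p(-pv))
    .agNew(p$tape, v, list(p),
           function(g) list(g * (pv - x) / (pv * (1 - pv))))
}

# NB log-pmf in mean/dispersion form, used inside the fused NLL nodes.
.nbLogPmf <- function(x, mu, theta) {
    lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
        theta * (log(theta) - log(theta + mu)) +
        x * (log(mu) - log(theta + mu))
}

.nbDLogPmfDMu <- function(x, mu, theta) x / mu - (x + theta) / (theta + mu)

.nbDLogPmfDTheta <- function(x, mu, theta) {
    digamma(x + theta) - digamma(theta) + log(theta) - log(theta + mu) +
        1 - (x + theta) / (theta + mu)
}

# Zero-inflated NB negative log-likelihood, summed over all entries.
# pi, mu, theta are N x d nodes (pi in (0,1), mu/theta positive).
agZinbNLL <- function(pi, mu, theta, x) {
    if (min(x) < 0 || any(x != round(x)))
        stop("ZINB target must contain non-negative integer counts")
    pv <- agValue(pi); mv <- agValue(mu); tv <- agValue(theta)
    z <- x == 0
    nz <- !z
    lognb <- .nbLogPmf(x, mv, tv)
    # x = 0: -log(pi + (1-pi) NB(0));  x > 0: -log(1-pi) - log NB(x)
    p0 <- exp(tv * (log(tv) - log(tv + mv)))
    denom0 <- pv + (1 - pv) * p0
    v <- sum(-log(denom0) * z) + sum((-log1p(-pv) - lognb) * nz)
    .agNew(pi$tape, v, list(pi, mu, theta), function(g) {
        dpi <- -z * (1 - p0) / denom0 + nz / (1 - pv)
        dmu <- z * (1 - pv) * p0 * tv / (tv + mv) / denom0 -
            nz * .nbDLogPmfDMu(x, mv, tv)
        dlp0dth <- log(tv) + 1 - log(tv + mv) - tv / (tv + mv)
        dth <- -z * (1 - pv) * p0 * dlp0dth / denom0 -
            nz * .nbDLogPmfDTheta(x, mv, tv)
        list(g * dpi, g * dmu, g * dth)
    })
}

# Two-component NB mixture NLL (background/foreground means, shared
# per-feature dispersion phi as a length-d node), summed over entries.
agNBMixNLL <- function(nuB, nuF, piMix, phi, x) {
    if (min(x) < 0 || any(x != round(x)))
        stop("NB-mixture target must contain non-negative integer counts")
    nb <- agValue(nuB); nf <- agValue(nuF)
    pv <- agValue(piMix); ph <- agValue(phi)
    PH <- matrix(ph, nrow(x), ncol(x), byrow = TRUE)
    lb <- log(pv) + .nbLogPmf(x, nb, PH)
    lf <- log1p(-pv) + .nbLogPmf(x, nf, PH)
    mx <- pmax(lb, lf)
    le <- mx + log(exp(lb - mx) + exp(lf - mx))
    v <- -sum(le)
    .agNew(nuB$tape, v, list(nuB, nuF, piMix, phi), function(g) {
        rb <- exp(lb - le)
        rf <- 1 - rb
        dnb <- -rb * .nbDLogPmfDMu(x, nb, PH)
        dnf <- -rf * .nbDLogPmfDMu(x, nf, PH)
        dpi <- -(rb / pv - rf / (1 - pv))
        dphM <- -(rb * .nbDLogPmfDTheta(x, nb, PH) +
                  rf * .nbDLogPmfDTheta(x, nf, PH))
        list(g * dnb, g * dnf, g * dpi, g * colSums(dphM))
    })
}

# KL( lognormal(m, s) || lognormal(mPrior, sPrior) ), Gaussian KL on the
# log scale, summed over all entries; priors are per-feature constants.
agKLLognormal <- function(m, s, mPrior, sPrior) {
    mv <- agValue(m); sv <- agValue(s)
    MP <- matrix(mPrior, nrow(mv), ncol(mv), byrow = TRUE)
    SP <- matrix(sPrior, nrow(mv), ncol(mv), byrow = TRUE)
    v <- sum(log(SP / sv) + (sv^2 + (mv - MP)^2) / (2 * SP^2) - 0.5)
    .agNew(m$tape, v, list(m, s), function(g) {
        list(g * (mv - MP) / SP^2, g * (sv / SP^2 - 1 / sv))
    })
}

# Row-normalised Gram discrepancy: || C1n C1n' - C2n C2n' ||_F^2 / N^2.
agCommonalityLoss <- function(C1, C2) {
    c1 <- agValue(C1); c2 <- agValue(C2)
    n <- nrow(c1)
    r1 <- sqrt(rowSums(c1^2)); r2 <- sqrt(rowSums(c2^2))
    d1 <- ifelse(r1 > 0, r1, 1); d2 <- ifelse(r2 > 0, r2, 1)
    n1 <- c1 / d1; n2 <- c2 / d2
    Gd <- tcrossprod(n1) - tcrossprod(n2)
    v <- sum(Gd^2) / n^2
    .agNew(C1$tape, v, list(C1, C2), function(g) {
        dG <- 2 * Gd / n^2          # symmetric
        dn1 <- 2 * dG %*% n1
        dn2 <- -2 * dG %*% n2
        # back through row normalisation (zero rows get zero gradient)
        bn <- function(dn, nn, r, d) {
            out <- (dn - rowSums(dn * nn) * nn) / d
            out[r == 0, ] <- 0
            out
        }
        list(g * bn(dn1, n1, r1, d1), g * bn(dn2, n2, r2, d2))
    })
}

# Median pairwise embedding distance, the bandwidth of Q. For large N the
# median is taken over an evenly-spaced deterministic subsample of rows
# (the bandwidth is a scale statistic; the subsampled median is within
# sampling error of the full one at a fraction of the O(N^2) cost).
.embMedianDist <- function(Zv, maxRows = 1024L) {
    n <- nrow(Zv)
    if (n > maxRows) {
        idx <- unique(round(seq(1, n, length.out = maxRows)))
        Zv <- Zv[idx, , drop = FALSE]
    }
    stats::median(stats::dist(Zv))
}

# Spatial proximity regulariser: sum_ij P_ij (1 - Q_ij) / N^2 with
# Q_ij = exp(-||Z_i - Z_j||^2 / (2 sigma^2)), sigma = median pairwise
# embedding distance (treated as a constant during differentiation).
# P is a constant sparse proximity matrix (the Gaussian spatial kernel);
# only its nonzero pattern contributes.
agSpatialReg <- function(Z, P) {
    Zv <- agValue(Z)
    n <- nrow(Zv)
    # force general storage: symmetric sparse classes keep one triangle
    # only, which would silently halve the pair sum
    Pt <- methods::as(methods::as(P, "generalMatrix"), "TsparseMatrix")
    ii <- Pt@i + 1L; jj <- Pt@j + 1L; pw <- Pt@x
    sigma <- .embMedianDist(Zv)
    if (!is.finite(sigma) || sigma < 1e-12) {
        # all embeddings coincide: Q = 1 everywhere, zero loss, zero grad
        return(.agNew(Z$tape, 0, list(Z),
                      function(g) list(matrix(0, n, ncol(Zv)))))
    }
    d2 <- rowSums((Zv[ii, , drop = FALSE] - Zv[jj, , drop = FALSE])^2)
    q <- exp(-d2 / (2 * sigma^2))
    v <- sum(pw * (1 - q)) / n^2
    .agNew(Z$tape, v, list(Z), function(g) {
        wx <- pw * q
        Wm <- sparseMatrix(i = ii, j = jj, x = wx, dims = c(n, n))
        dZ <- (2 / (sigma^2 * n^2)) *
            (Matrix::rowSums(Wm) * Zv - as.matrix(Wm %*% Zv))
        list(g * dZ)
    })
}

# Literal variant: weights pairs by raw spatial distance D_ij (dense).
agSpatialRegLiteral <- function(Z, Ddist) {
    Zv <- agValue(Z)
    n <- nrow(Zv)
    sigma <- .embMedianDist(Zv)
    if (!is.finite(sigma) || sigma < 1e-12)
        return(.agNew(Z$tape, 0, list(Z),
                      function(g) list(matrix(0, n, ncol(Zv)))))
    G <- tcrossprod(Zv)
    sq <- diag(G)
    d2 <- outer(sq, sq, `+`) - 2 * G
    d2[d2 < 0] <- 0
    Q <- exp(-d2 / (2 * sigma^2))
    v <- sum(Ddist * (1 - Q)) / n^2
    .agNew(Z$tape, v, list(Z), function(g) {
        Wm <- Ddist * Q
        dZ <- (2 / (sigma^2 * n^2)) * (rowSums(Wm) * Zv - Wm %*% Zv)
        list(g * dZ)
    })
}

# ---- finite-difference checker (used by tests) ------------------------

# forward: function(list-of-leaf-values) -> scalar; returns max relative
# discrepancy between autodiff and central differences.
agGradCheck <- function(forward, leafValues, eps = 1e-5) {
    tape <- agTape()
    leaves <- lapply(leafValues, function(v) agLeaf(tape, v))
    root <- forward(leaves)
    grads <- agBackward(root)
    worst <- 0
    for (k in seq_along(leaves)) {
        gk <- grads[[leaves[[k]]$id]]
        if (is.null(gk)) gk <- 0 * leafValues[[k]]
        v0 <- leafValues[[k]]
        num <- v0
        for (idx in seq_along(v0)) {
            vp <- leafValues; vp[[k]][idx] <- v0[idx] + eps
            vm <- leafValues; vm[[k]][idx] <- v0[idx] - eps
            tp <- agTape()
            fp <- forward(lapply(vp, function(v) agLeaf(tp, v)))
            tm <- agTape()
            fm <- forward(lapply(vm, function(v) agLeaf(tm, v)))
            num[idx] <- (agValue(fp) - agValue(fm)) / (2 * eps)
        }
        scale <- pmax(abs(num), abs(gk), 1e-4)
        worst <- max(worst, max(abs(num - gk) / scale))
    }
    worst
}
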